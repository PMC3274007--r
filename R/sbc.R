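#' Segment-based classification by majority rule
#'
#' The fusion step of the pipeline: for every segment, the pixel-based
#' classification labels of its pixels are counted and the whole segment is
#' reassigned to the plurality (modal) class.  "Majority" means plurality:
#' the modal class is painted even when it holds no absolute majority, so no
#' segment is left unassigned.  Ties are broken towards the smallest class
#' id.  Pixels labeled 0 (nodata) are excluded from the counts; a segment
#' containing only such pixels keeps label 0, and pixels outside every
#' segment (segment id 0) keep their input label.
#'
#' Applying the rule twice with the same segment map is idempotent, and the
#' output is piecewise-constant on segments by construction.
#'
#' @param classified a [label_raster()], normally from [ml_classify()].
#' @param segmap a `segment_map` from [segment_scene()].
#' @return a [label_raster()] constant within each segment.
#' @export
segment_majority <- function(classified, segmap) {
  stopifnot(inherits(classified, "label_raster"))
  lab <- classified$labels
  ids <- segmap$segment_ids
  if (!all(dim(lab) == dim(ids))) stop("dimension mismatch")
  keep <- ids > 0L & lab > 0L
  out <- lab
  if (any(keep)) {
    counts <- table(factor(ids[keep], levels = seq_len(max(ids))),
                    factor(lab[keep], levels = sort(unique(lab[keep]))))
    cls <- as.integer(colnames(counts))
    # max.col with "first" + increasing class-id columns = smallest-id ties
    winner <- integer(nrow(counts))
    nz <- rowSums(counts) > 0
    winner[nz] <- cls[max.col(counts[nz, , drop = FALSE],
                              ties.method = "first")]
    pos <- ids > 0L
    w <- winner[ids[pos]]
    keep_old <- w == 0L          # segment with only nodata labels
    out[pos] <- ifelse(keep_old, lab[pos], w)
  }
  label_raster(out, scheme = classified$scheme)
}
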