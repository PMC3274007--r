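#' Segmentation parameters
#'
#' Parameters of the multiresolution region-growing criterion.  The merge
#' cost splits between spectral ("colour") and geometric ("shape")
#' heterogeneity with weight `w_color` (shape weight is `1 - w_color`); the
#' shape term splits between compactness and smoothness with weight
#' `w_compact` (smoothness weight `1 - w_compact`).  A merge is accepted
#' only while its cost is strictly below `scale^2`, so larger scales give
#' larger image objects.
#'
#' @param scale positive scale parameter (unitless, on the DN scale of the
#'   imagery).
#' @param w_color colour weight in `[0, 1]`.
#' @param w_compact compactness weight in `[0, 1]`.
#' @param band_weights non-negative per-band weights for the colour term
#'   (recycled to B by the segmenter when a scalar); not all zero.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(scale, w_color = 0.5, w_compact = 0.5,
                                band_weights = 1) {
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be > 0")
  if (w_color < 0 || w_color > 1) stop("`w_color` must lie in [0, 1]")
  if (w_compact < 0 || w_compact > 1) stop("`w_compact` must lie in [0, 1]")
  if (any(band_weights < 0) || all(band_weights == 0))
    stop("band weights must be non-negative and not all zero")
  structure(list(scale = scale, w_color = w_color, w_compact = w_compact,
                 band_weights = band_weights),
            class = "segmentation_params")
}

#' Per-segment incremental statistics
#'
#' The sufficient statistics from which merge costs are computed without
#' revisiting pixels: pixel count, per-band sum and sum of squares, exposed
#' edge perimeter, and bounding box.  Standard deviations use the population
#' convention (divide by n), which makes single-pixel sigma = 0 exact.
#'
#' @param n pixel count (>= 1).
#' @param sum,sumsq numeric B-vectors of per-band sums and sums of squares.
#' @param perimeter count of exposed pixel edges (4 for a single pixel).
#' @param bbox integer vector `(row_min, row_max, col_min, col_max)`, 1-based.
#' @return object of class `segment_stats`.
#' @export
segment_stats <- function(n, sum, sumsq, perimeter, bbox) {
  if (n < 1) stop("`n` must be >= 1")
  if (length(sum) != length(sumsq)) stop("sum/sumsq length mismatch")
  if (any(sumsq < sum^2 / n - 1e-8 * pmax(1, abs(sumsq))))
    stop("sum of squares inconsistent with sum")
  if (perimeter < 4) stop("perimeter must be >= 4")
  if (length(bbox) != 4 || bbox[1] > bbox[2] || bbox[3] > bbox[4])
    stop("invalid bounding box")
  structure(list(n = n, sum = as.numeric(sum), sumsq = as.numeric(sumsq),
                 perimeter = perimeter, bbox = as.integer(bbox)),
            class = "segment_stats")
}

sd_pop <- function(n, s, q) {
  v <- q / n - (s / n)^2
  sqrt(pmax(v, 0))
}

bbox_perimeter <- function(bbox) {
  2 * ((bbox[2] - bbox[1] + 1) + (bbox[4] - bbox[3] + 1))
}

#' Cost of merging two segments
#'
#' The heterogeneity increase of fusing segments `a` and `b` into `m`:
#' \deqn{\Delta h_{color} = \sum_b w_b [\, n_m\sigma_b(m) - n_a\sigma_b(a) -
#'   n_b\sigma_b(b)\,]}
#' \deqn{h_{cmp} = l/\sqrt n, \quad h_{smooth} = l/b, \quad
#'   \Delta h_x = n_m h_x(m) - n_a h_x(a) - n_b h_x(b)}
#' \deqn{cost = w_{color}\,\Delta h_{color} + (1 - w_{color})
#'   [\,w_{cmp}\Delta h_{cmp} + (1-w_{cmp})\Delta h_{smooth}\,]}
#' with \eqn{\sigma_b} the population standard deviation in band b, `l` the
#' exposed-edge perimeter, and `b` the bounding-box perimeter.  The merged
#' perimeter is `l_a + l_b - 2 * shared_edges`.  The colour term is
#' non-negative by variance pooling; the total is clamped at 0.
#'
#' @param a,b [segment_stats()] of the two segments.
#' @param params [segmentation_params()] (the scale is not used here).
#' @param shared_edges number of pixel edges shared by `a` and `b`.
#' @return non-negative merge cost.
#' @export
merge_cost <- function(a, b, params, shared_edges = 1) {
  stopifnot(inherits(a, "segment_stats"), inherits(b, "segment_stats"),
            inherits(params, "segmentation_params"))
  B <- length(a$sum)
  wb <- rep_len(params$band_weights, B)
  nm <- a$n + b$n
  dcol <- sum(wb * (nm * sd_pop(nm, a$sum + b$sum, a$sumsq + b$sumsq) -
                    a$n * sd_pop(a$n, a$sum, a$sumsq) -
                    b$n * sd_pop(b$n, b$sum, b$sumsq)))
  dcol <- max(dcol, 0)
  lm <- a$perimeter + b$perimeter - 2 * shared_edges
  bbox_m <- c(min(a$bbox[1], b$bbox[1]), max(a$bbox[2], b$bbox[2]),
              min(a$bbox[3], b$bbox[3]), max(a$bbox[4], b$bbox[4]))
  dcmp <- nm * lm / sqrt(nm) -
    a$n * a$perimeter / sqrt(a$n) - b$n * b$perimeter / sqrt(b$n)
  dsm <- nm * lm / bbox_perimeter(bbox_m) -
    a$n * a$perimeter / bbox_perimeter(a$bbox) -
    b$n * b$perimeter / bbox_perimeter(b$bbox)
  dshape <- params$w_compact * dcmp + (1 - params$w_compact) * dsm
  max(params$w_color * dcol + (1 - params$w_color) * dshape, 0)
}

new_segment_map <- function(ids, stats, adjacency) {
  structure(list(segment_ids = ids, stats = stats, adjacency = adjacency),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("segment_map: %d x %d, %d segment(s), mean area %.1f px\n",
              nrow(x$segment_ids), ncol(x$segment_ids), nrow(x$stats),
              mean(x$stats$n)))
  invisible(x)
}

#' Number of segments in a segment map
#' @param map a `segment_map`.
#' @return integer count.
#' @export
n_segments <- function(map) nrow(map$stats)

stats_df_from_cpp <- function(res, band_names) {
  B <- ncol(res$sum)
  df <- data.frame(id = seq_along(res$n), n = res$n,
                   perimeter = res$perimeter,
                   row_min = res$rmin, row_max = res$rmax,
                   col_min = res$cmin, col_max = res$cmax)
  for (b in seq_len(B)) {
    df[[paste0("sum.", band_names[b])]] <- res$sum[, b]
    df[[paste0("sumsq.", band_names[b])]] <- res$ssq[, b]
    df[[paste0("mean.", band_names[b])]] <- res$sum[, b] / res$n
  }
  df
}

#' Initial single-pixel segmentation
#'
#' One segment per valid pixel: exact statistics (sigma = 0), perimeter 4,
#' and a 4-neighbour adjacency.  Nodata pixels take id 0 and are excluded.
#' This is the starting state of the region-growing segmenter and is also
#' useful as the identity segmentation.
#'
#' @param scene a [multiband_scene()].
#' @return a `segment_map`: integer `segment_ids` matrix (ids 1..K assigned
#'   in column-major order), a `stats` data.frame (id, n, perimeter, bbox,
#'   per-band sum/sumsq/mean), and an `adjacency` list of neighbour ids.
#' @export
init_segments <- function(scene) {
  stopifnot(inherits(scene, "multiband_scene"))
  res <- .segment_cpp(as.vector(scene$pixels), as.vector(scene$nodata_mask),
                      nrow(scene$nodata_mask), ncol(scene$nodata_mask),
                      dim(scene$pixels)[3], 0, 1, 0.5, rep(1, dim(scene$pixels)[3]),
                      1)
  new_segment_map(res$ids, stats_df_from_cpp(res, scene$band_names),
                  res$adjacency)
}

#' Multiresolution region-growing segmentation
#'
#' Starting from single-pixel objects, repeatedly merges neighbouring
#' objects by local mutual best fitting: in each pass the surviving objects
#' are visited in a seeded pseudo-random order, and an object fuses with its
#' minimum-cost neighbour (see [merge_cost()]) only when the choice is
#' mutual and the cost is strictly below `scale^2`; ties are broken towards
#' the smallest object id.  Passes repeat until a full pass makes no merge.
#' The randomized visiting order avoids scanline artifacts while staying
#' reproducible under `rng_seed`.
#'
#' @param scene a [multiband_scene()].
#' @param params a [segmentation_params()].
#' @param rng_seed integer seed for the visiting order.
#' @return a `segment_map` (see [init_segments()] for the fields); segment
#'   ids are renumbered 1..K by first occurrence in column-major order.
#' @export
segment_scene <- function(scene, params, rng_seed = 1L) {
  stopifnot(inherits(scene, "multiband_scene"),
            inherits(params, "segmentation_params"))
  B <- dim(scene$pixels)[3]
  wb <- rep_len(params$band_weights, B)
  res <- .segment_cpp(as.vector(scene$pixels), as.vector(scene$nodata_mask),
                      nrow(scene$nodata_mask), ncol(scene$nodata_mask), B,
                      params$scale, params$w_color, params$w_compact, wb,
                      as.double(rng_seed))
  new_segment_map(res$ids, stats_df_from_cpp(res, scene$band_names),
                  res$adjacency)
}

#' Per-segment band means
#'
#' Exact per-segment, per-band mean DN computed directly from the pixels.
#'
#' @param map a `segment_map`.
#' @param scene the matching [multiband_scene()].
#' @return numeric K x B matrix, row i = mean vector of segment id i.
#' @export
segment_means <- function(map, scene) {
  stopifnot(inherits(scene, "multiband_scene"))
  if (!all(dim(map$segment_ids) == dim(scene$pixels)[1:2]))
    stop("segment map and scene dimensions differ")
  X <- scene_band_matrix(scene)
  ids <- as.vector(map$segment_ids)
  keep <- ids > 0L
  sums <- rowsum(X[keep, , drop = FALSE], ids[keep])
  cnt <- tabulate(ids[keep])
  m <- sums / cnt[as.integer(rownames(sums))]
  colnames(m) <- scene$band_names
  m
}

#' Export per-segment statistics as CSV
#'
#' Writes id, area, perimeter and per-band means, one row per segment.
#' @param map a `segment_map`.
#' @param path destination CSV path.
#' @export
write_segment_stats <- function(map, path) {
  keep <- c("id", "n", "perimeter",
            grep("^mean\\.", names(map$stats), value = TRUE))
  write.csv(map$stats[keep], path, row.names = FALSE)
  invisible(path)
}

#' Boundary recall of a segmentation against a reference partition
#'
#' Fraction of reference boundaries (4-neighbour pixel pairs whose reference
#' labels differ) that are also segment boundaries.  Used to quantify how
#' well a segmentation respects true stand edges.
#'
#' @param map a `segment_map`.
#' @param reference a [label_raster()] (e.g. the ground-truth stand mosaic).
#' @return fraction in `[0, 1]` (NA when the reference has no boundaries).
#' @export
boundary_recall <- function(map, reference) {
  ref <- if (inherits(reference, "label_raster")) reference$labels else reference
  ids <- map$segment_ids
  if (!all(dim(ref) == dim(ids))) stop("dimension mismatch")
  H <- nrow(ref); W <- ncol(ref)
  rv <- ref[-H, ] != ref[-1, ]; rh <- ref[, -W] != ref[, -1]
  sv <- ids[-H, ] != ids[-1, ]; sh <- ids[, -W] != ids[, -1]
  tot <- sum(rv) + sum(rh)
  if (tot == 0) return(NA_real_)
  (sum(sv & rv) + sum(sh & rh)) / tot
}
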