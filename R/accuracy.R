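#' Allocate test clusters per class
#'
#' Follows the rule of thumb of roughly 50 test units per class, scaled by
#' each class's area share of the reference map with a floor: class i gets
#' `max(floor, round(base * K * share_i))` clusters, K the number of classes.
#' Under equal shares every class gets `base`.
#'
#' @param reference a [label_raster()] ground-truth map.
#' @param base nominal per-class count (default 50).
#' @param floor minimum per-class count (default 5).
#' @return named integer vector (names = class ids) for the classes present.
#' @export
allocate_test_counts <- function(reference, base = 50, floor = 5) {
  lab <- reference$labels
  tab <- tabulate(lab[lab > 0L], nbins = max(reference$scheme$id))
  present <- which(tab > 0)
  share <- tab[present] / sum(tab)
  n <- pmax(floor, round(base * length(present) * share))
  setNames(as.integer(n), present)
}

#' Sample homogeneous test clusters
#'
#' Places square test windows of `(2*half_width + 1)^2` pixels (default 9x9)
#' at random such that each window lies wholly inside a single
#' reference-class region — and, when `segmap` is supplied, wholly inside a
#' single segment — emulating field-verified cluster sampling.  Windows do
#' not overlap.  The cluster's reference class is the modal reference label
#' in the window (trivially the single class present).
#'
#' @param reference a [label_raster()] ground-truth map.
#' @param n_per_class named integer vector (names = class ids) of requested
#'   cluster counts, e.g. from [allocate_test_counts()]; a single unnamed
#'   number applies to every class present.
#' @param half_width window half width in pixels (default 4, i.e. 9x9).
#' @param segmap optional `segment_map` the windows must also respect.
#' @param rng_seed integer seed.
#' @param strict if `TRUE` (default) a class with no candidate window at all
#'   is an error naming the class; if `FALSE` it is skipped with a warning
#'   (useful on small simulated landscapes where a rare class may occupy
#'   only slivers).
#' @return data.frame of class `test_clusters` with columns `row`, `col`
#'   (window centres), `half_width`, `reference_class`.  If a class's quota
#'   cannot be met the sample is partial with a warning.
#' @export
sample_test_clusters <- function(reference, n_per_class, half_width = 4L,
                                 segmap = NULL, rng_seed = 1L, strict = TRUE) {
  stopifnot(inherits(reference, "label_raster"))
  lab <- reference$labels
  H <- nrow(lab); W <- ncol(lab)
  w <- 2L * half_width + 1L
  if (H < w || W < w) stop("raster smaller than the cluster window")
  hom <- window_homogeneous(lab, half_width)
  if (!is.null(segmap))
    hom <- hom & window_homogeneous(segmap$segment_ids, half_width)
  present <- sort(unique(lab[lab > 0L]))
  if (is.null(names(n_per_class))) {
    n_per_class <- setNames(rep(as.integer(n_per_class), length(present)),
                            present)
  }
  centres <- which(hom, arr.ind = TRUE)
  if (nrow(centres)) centres <- centres[lab[centres] > 0L, , drop = FALSE]
  taken_r <- integer(0); taken_c <- integer(0)
  rows <- list()
  with_seed(rng_seed, {
    for (cl in as.integer(names(n_per_class))) {
      want <- n_per_class[[as.character(cl)]]
      if (want < 1) next
      cand <- centres[lab[centres] == cl, , drop = FALSE]
      if (nrow(cand) == 0) {
        msg <- paste0("no candidate cluster window for class ",
                      reference$scheme$abbreviation[cl])
        if (strict) stop(msg)
        warning(msg)
        next
      }
      ord <- sample.int(nrow(cand))
      got <- 0L
      for (i in ord) {
        if (got >= want) break
        r <- cand[i, 1]; c <- cand[i, 2]
        if (any(abs(taken_r - r) < w & abs(taken_c - c) < w)) next
        taken_r <- c(taken_r, r); taken_c <- c(taken_c, c)
        rows[[length(rows) + 1L]] <- data.frame(row = r, col = c,
                                                half_width = half_width,
                                                reference_class = cl)
        got <- got + 1L
      }
      if (got < want)
        warning(sprintf("class %s: placed %d of %d requested clusters",
                        reference$scheme$abbreviation[cl], got, want))
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no clusters could be placed")
  rownames(out) <- NULL
  attr(out, "scheme") <- reference$scheme
  class(out) <- c("test_clusters", "data.frame")
  out
}

# TRUE at centres whose (2h+1)^2 window lies inside the raster and contains a
# single value of `m`; computed with separable running min/max filters.
window_homogeneous <- function(m, h) {
  H <- nrow(m); W <- ncol(m)
  mn <- mx <- m
  # out-of-raster cells pad the min with -Inf and the max with +Inf, so any
  # window touching the border is rejected (it must lie fully inside)
  run <- function(mn, mx, dr, dc) {
    sh_mn <- matrix(-Inf, H, W); sh_mx <- matrix(Inf, H, W)
    r_src <- seq_len(H) + dr; c_src <- seq_len(W) + dc
    ok_r <- r_src >= 1 & r_src <= H; ok_c <- c_src >= 1 & c_src <= W
    sh_mn[ok_r, ok_c] <- mn[r_src[ok_r], c_src[ok_c]]
    sh_mx[ok_r, ok_c] <- mx[r_src[ok_r], c_src[ok_c]]
    list(mn = sh_mn, mx = sh_mx)
  }
  amn <- matrix(Inf, H, W); amx <- matrix(-Inf, H, W)
  for (dr in -h:h) {
    s <- run(mn, mx, dr, 0L)
    amn <- pmin(amn, s$mn); amx <- pmax(amx, s$mx)
  }
  bmn <- matrix(Inf, H, W); bmx <- matrix(-Inf, H, W)
  for (dc in -h:h) {
    sh_mn <- matrix(-Inf, H, W); sh_mx <- matrix(Inf, H, W)
    c_src <- seq_len(W) + dc; ok_c <- c_src >= 1 & c_src <= W
    sh_mn[, ok_c] <- amn[, c_src[ok_c]]
    sh_mx[, ok_c] <- amx[, c_src[ok_c]]
    bmn <- pmin(bmn, sh_mn); bmx <- pmax(bmx, sh_mx)
  }
  is.finite(bmn) & is.finite(bmx) & bmn == bmx
}

# modal label of the cluster window on `lab`; ties to smallest id; 0 ignored
window_mode <- function(lab, row, col, h) {
  win <- lab[(row - h):(row + h), (col - h):(col + h)]
  win <- win[win > 0L]
  if (!length(win)) return(0L)
  tab <- tabulate(win)
  which.max(tab)   # first max = smallest id
}

#' Build an error matrix from test clusters
#'
#' Each cluster contributes exactly one count at (modal classified class in
#' its window, reference class): rows are classified, columns reference, in
#' class-scheme order, matching the conventional error-matrix layout.
#'
#' @param classified a [label_raster()].
#' @param clusters a `test_clusters` data.frame from
#'   [sample_test_clusters()].
#' @param scheme a [class_scheme()]; defaults to the classified map's.
#' @return object of class `error_matrix`: a K x K integer matrix with
#'   abbreviation dimnames, grand total = number of clusters.
#' @export
build_error_matrix <- function(classified, clusters,
                               scheme = classified$scheme) {
  stopifnot(inherits(classified, "label_raster"))
  if (is.null(clusters) || nrow(clusters) == 0) stop("empty cluster list")
  K <- max(scheme$id)
  m <- matrix(0L, K, K,
              dimnames = list(classified = scheme$abbreviation,
                              reference = scheme$abbreviation))
  for (i in seq_len(nrow(clusters))) {
    cc <- window_mode(classified$labels, clusters$row[i], clusters$col[i],
                      clusters$half_width[i])
    rc <- clusters$reference_class[i]
    if (cc >= 1 && rc >= 1) m[cc, rc] <- m[cc, rc] + 1L
  }
  error_matrix(m, scheme)
}

#' Construct an error matrix object
#'
#' @param counts K x K matrix of non-negative counts, rows = classified,
#'   columns = reference, in class-id order.
#' @param scheme a [class_scheme()] giving the class order.
#' @return an `error_matrix`.
#' @export
error_matrix <- function(counts, scheme = default_class_scheme()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("error matrix must be square")
  if (any(counts < 0)) stop("error matrix entries must be >= 0")
  if (nrow(counts) != nrow(scheme)) stop("matrix order does not match scheme")
  dimnames(counts) <- list(classified = scheme$abbreviation,
                           reference = scheme$abbreviation)
  structure(counts, class = c("error_matrix", class(counts)), scheme = scheme)
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("error_matrix: %d classes, %d test units\n", nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Overall accuracy of an error matrix
#'
#' `trace(m) / sum(m)`, the fraction of test units whose classified and
#' reference classes agree.
#'
#' @param m an [error_matrix()] (any square count matrix is accepted).
#' @return fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(m) {
  if (sum(m) == 0) stop("error matrix has zero total")
  sum(diag(as.matrix(m))) / sum(m)
}

#' Cohen's kappa (K-HAT) of an error matrix
#'
#' Chance-corrected agreement
#' \deqn{\kappa = (p_o - p_e)/(1 - p_e),\quad p_o = trace(m)/N,\quad
#'   p_e = \sum_i r_i c_i / N^2}
#' with \eqn{r_i, c_i} the row and column totals.  Undefined (error) when
#' `p_e == 1`, which happens when all mass sits in a single row/column pair.
#'
#' @inheritParams overall_accuracy
#' @return kappa in `[-1, 1]`.
#' @export
kappa_statistic <- function(m) {
  m <- as.matrix(m)
  N <- sum(m)
  if (N == 0) stop("error matrix has zero total")
  po <- sum(diag(m)) / N
  pe <- sum(rowSums(m) * colSums(m)) / N^2
  if (1 - pe <= .Machine$double.eps)
    stop("kappa undefined: chance agreement p_e = 1")
  (po - pe) / (1 - pe)
}

#' Per-class user's and producer's accuracy
#'
#' User's accuracy of class i is `m[i,i] / rowSum_i` (commission view);
#' producer's accuracy is `m[i,i] / colSum_i` (omission view).  Classes with
#' an empty margin are reported as `NA`.
#'
#' @inheritParams overall_accuracy
#' @return data.frame with columns `class`, `users_pct`, `producers_pct`.
#' @export
users_producers <- function(m) {
  m <- as.matrix(m)
  rs <- rowSums(m); cs <- colSums(m); d <- diag(m)
  data.frame(class = rownames(m) %||% seq_len(nrow(m)),
             users_pct = ifelse(rs > 0, 100 * d / rs, NA_real_),
             producers_pct = ifelse(cs > 0, 100 * d / cs, NA_real_),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write an error matrix CSV
#'
#' CSV with a header row and first column of class abbreviations; rows are
#' classified classes, columns reference classes.
#'
#' @param path CSV path.
#' @param scheme a [class_scheme()].
#' @export
read_error_matrix <- function(path, scheme = default_class_scheme()) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  error_matrix(as.matrix(df), scheme)
}

#' @rdname read_error_matrix
#' @param m an [error_matrix()].
#' @export
write_error_matrix <- function(m, path) {
  write.csv(as.data.frame(unclass(m)), path, quote = FALSE)
  invisible(path)
}

#' Pixel-wise error matrix against a full reference map
#'
#' Cross-tabulates classified versus reference class over every valid pixel
#' (both labels nonzero).  This is the natural accuracy assessment when the
#' complete ground truth is known, as on simulated scenes; cluster sampling
#' ([sample_test_clusters()]) mirrors the field protocol instead.
#'
#' @param classified,reference [label_raster()] objects on the same grid.
#' @return an [error_matrix()] whose total is the number of valid pixels.
#' @export
pixel_error_matrix <- function(classified, reference) {
  stopifnot(inherits(classified, "label_raster"),
            inherits(reference, "label_raster"))
  cl <- as.vector(classified$labels); rf <- as.vector(reference$labels)
  if (length(cl) != length(rf)) stop("dimension mismatch")
  keep <- cl > 0L & rf > 0L
  if (!any(keep)) stop("no jointly labeled pixels")
  K <- max(reference$scheme$id)
  m <- matrix(0L, K, K)
  tab <- table(factor(cl[keep], levels = seq_len(K)),
               factor(rf[keep], levels = seq_len(K)))
  m[] <- as.integer(tab)
  error_matrix(m, reference$scheme)
}

#' Accuracy report for one classified map
#'
#' Convenience wrapper: error matrix, overall accuracy, kappa and per-class
#' accuracies for a classified map against sampled clusters.
#'
#' @inheritParams build_error_matrix
#' @return list with `matrix`, `overall_accuracy`, `kappa`, `per_class`.
#' @export
assess_classification <- function(classified, clusters,
                                  scheme = classified$scheme) {
  m <- build_error_matrix(classified, clusters, scheme)
  list(matrix = m, overall_accuracy = overall_accuracy(m),
       kappa = kappa_statistic(m), per_class = users_producers(m))
}
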