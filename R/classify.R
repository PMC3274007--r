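#' Estimate class spectral signatures from training areas
#'
#' Per-class sample mean and covariance (n - 1 denominator) over the
#' training pixels, plus class priors.  Classes with fewer than `B + 1`
#' training pixels are flagged with a warning because their covariance is
#' rank-deficient; the maximum-likelihood discriminant then relies on the
#' regularization described in [ml_classify()].
#'
#' @param scene a [multiband_scene()].
#' @param training a [label_raster()] of training pixels (0 = not training).
#' @param prior_mode `"equal"` or `"proportional"` (to training pixel counts).
#' @return object of class `class_signature_set`: a list with `class_ids`,
#'   `means` (K x B), `covariances` (list of B x B), `n_training`, `priors`,
#'   `band_names`, `scheme`.
#' @export
extract_signatures <- function(scene, training,
                               prior_mode = c("equal", "proportional")) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(scene, "multiband_scene"),
            inherits(training, "label_raster"))
  if (!all(dim(training$labels) == dim(scene$pixels)[1:2]))
    stop("training raster and scene dimensions differ")
  X <- scene_band_matrix(scene)
  lab <- as.vector(training$labels)
  lab[scene$nodata_mask] <- 0L
  present <- sort(unique(lab[lab != 0L]))
  if (!length(present)) stop("no training pixels")
  B <- ncol(X)
  cnt <- vapply(present, function(cl) sum(lab == cl), integer(1))
  too_few <- present[cnt < 2]
  if (length(too_few))
    stop("cannot estimate a signature from < 2 pixels for class(es): ",
         paste(training$scheme$abbreviation[too_few], collapse = ", "))
  flagged <- present[cnt < B + 1]
  if (length(flagged))
    warning("training count below B + 1 for class(es): ",
            paste(training$scheme$abbreviation[flagged], collapse = ", "))
  means <- t(vapply(present, function(cl) colMeans(X[lab == cl, , drop = FALSE]),
                    numeric(B)))
  covs <- lapply(present, function(cl) cov(X[lab == cl, , drop = FALSE]))
  priors <- if (prior_mode == "equal") rep(1 / length(present), length(present))
            else cnt / sum(cnt)
  structure(list(class_ids = present, means = means, covariances = covs,
                 n_training = cnt, priors = priors,
                 band_names = scene$band_names, scheme = training$scheme),
            class = "class_signature_set")
}

#' @export
print.class_signature_set <- function(x, ...) {
  cat(sprintf("class_signature_set: %d class(es), %d band(s), priors %s\n",
              length(x$class_ids), ncol(x$means),
              paste(signif(x$priors, 3), collapse = "/")))
  invisible(x)
}

#' Export / import signatures as CSV
#'
#' One row per class: id, prior, training count, per-band means, then the
#' row-major flattened covariance.
#' @param sigs a `class_signature_set`.
#' @param path CSV path.
#' @export
write_signatures <- function(sigs, path) {
  B <- ncol(sigs$means)
  cv <- t(vapply(sigs$covariances, function(S) as.vector(t(S)), numeric(B * B)))
  df <- data.frame(class_id = sigs$class_ids, prior = sigs$priors,
                   n_training = sigs$n_training)
  mu <- as.data.frame(sigs$means)
  names(mu) <- paste0("mean.", sigs$band_names)
  cvd <- as.data.frame(cv)
  names(cvd) <- paste0("cov.", as.vector(t(outer(sigs$band_names,
                                                 sigs$band_names, paste,
                                                 sep = "."))))
  write.csv(cbind(df, mu, cvd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @param scheme a [class_scheme()].
#' @export
read_signatures <- function(path, scheme = default_class_scheme()) {
  df <- read.csv(path)
  mu_cols <- grep("^mean\\.", names(df))
  cv_cols <- grep("^cov\\.", names(df))
  B <- length(mu_cols)
  structure(list(class_ids = as.integer(df$class_id),
                 means = as.matrix(df[mu_cols]),
                 covariances = lapply(seq_len(nrow(df)), function(i)
                   matrix(as.numeric(df[i, cv_cols]), B, B, byrow = TRUE)),
                 n_training = as.integer(df$n_training),
                 priors = df$prior,
                 band_names = sub("^mean\\.", "", names(df)[mu_cols]),
                 scheme = scheme),
            class = "class_signature_set")
}

# Gaussian log-discriminant of every class on rows of X:
#   g_i(x) = ln p_i - 0.5 ln|S_i| - 0.5 (x - mu_i)' S_i^{-1} (x - mu_i)
# Returns an N x K matrix.  Covariances whose Cholesky fails (or whose
# determinant underflows) are ridge-regularized by eps*I with
# eps = 1e-6 * trace(S)/B (falling back to 1e-6 for an all-zero S).
discriminant_matrix <- function(X, sigs) {
  K <- length(sigs$class_ids)
  B <- ncol(X)
  G <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    S <- sigs$covariances[[k]]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || !all(diag(ch) > sqrt(.Machine$double.xmin))) {
      eps <- 1e-6 * sum(diag(S)) / B
      if (eps <= 0) eps <- 1e-6
      S <- S + diag(eps, B)
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch))
        stop("singular covariance after regularization for class ",
             sigs$class_ids[k])
    }
    logdet <- 2 * sum(log(diag(ch)))
    Z <- forwardsolve(t(ch), t(X) - sigs$means[k, ])
    G[, k] <- log(sigs$priors[k]) - 0.5 * logdet - 0.5 * colSums(Z^2)
  }
  G
}

#' Maximum-likelihood pixel classification
#'
#' Assigns each valid pixel the class maximizing the Gaussian discriminant
#' \deqn{g_i(x) = \ln p_i - \tfrac12 \ln|\Sigma_i|
#'   - \tfrac12 (x-\mu_i)^\top \Sigma_i^{-1} (x-\mu_i).}
#' Ties are broken towards the smallest class id (a measure-zero event under
#' continuous noise).  Nodata pixels receive label 0.  Every pixel is
#' classified into one of the signature classes; there is no reject class.
#'
#' @param scene a [multiband_scene()].
#' @param sigs a `class_signature_set` from [extract_signatures()].
#' @return a [label_raster()] of the classified map.
#' @export
ml_classify <- function(scene, sigs) {
  stopifnot(inherits(scene, "multiband_scene"),
            inherits(sigs, "class_signature_set"))
  if (ncol(sigs$means) != dim(scene$pixels)[3])
    stop("signature bands do not match scene bands")
  X <- scene_band_matrix(scene)
  valid <- !as.vector(scene$nodata_mask)
  out <- integer(length(valid))
  if (any(valid)) {
    G <- discriminant_matrix(X[valid, , drop = FALSE], sigs)
    # columns are in increasing class id order, so "first" = smallest id
    out[valid] <- sigs$class_ids[max.col(G, ties.method = "first")]
  }
  label_raster(matrix(out, nrow(scene$nodata_mask)), scheme = sigs$scheme)
}

#' Majority (modal) filter
#'
#' Post-classification smoothing: each pixel is replaced by the modal class
#' of the surrounding `window x window` neighbourhood (truncated at the
#' raster edge).  Ties retain the centre pixel's class.  Label 0 (nodata)
#' pixels are not counted and are never introduced.
#'
#' @param classified a [label_raster()].
#' @param window odd window width >= 3 (default 3, the classic 3x3 filter).
#' @return a filtered [label_raster()].
#' @export
majority_filter <- function(classified, window = 3L) {
  stopifnot(inherits(classified, "label_raster"))
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  lab <- classified$labels
  H <- nrow(lab); W <- ncol(lab)
  K <- max(classified$scheme$id)
  h <- (window - 1L) / 2L
  counts <- array(0L, c(H, W, K))
  for (dr in -h:h) {
    rs <- pmin(pmax(seq_len(H) + dr, 0L), H + 1L)   # 0 / H+1 mark off-raster
    for (dc in -h:h) {
      cs <- pmin(pmax(seq_len(W) + dc, 0L), W + 1L)
      inside_r <- rs >= 1L & rs <= H
      inside_c <- cs >= 1L & cs <= W
      sh <- matrix(0L, H, W)
      sh[inside_r, inside_c] <- lab[rs[inside_r], cs[inside_c]]
      for (k in seq_len(K))
        counts[, , k] <- counts[, , k] + (sh == k)
    }
  }
  best <- apply(counts, c(1, 2), function(v) {
    m <- max(v)
    if (m == 0L) return(0L)
    w <- which(v == m)
    if (length(w) > 1L) -1L else w[1]
  })
  tie <- best == -1L
  best[tie] <- lab[tie]
  best[lab == 0L] <- 0L   # nodata pixels stay nodata
  label_raster(matrix(as.integer(best), H, W), scheme = classified$scheme)
}

#' Object-based maximum-likelihood classification
#'
#' Classifies each segment from its mean spectral vector with the same
#' Gaussian discriminant as [ml_classify()], then paints all its pixels with
#' that class.  With single-pixel segments this reduces exactly to
#' [ml_classify()].
#'
#' @param segmap a `segment_map` from [segment_scene()].
#' @param scene the matching [multiband_scene()].
#' @param sigs a `class_signature_set`.
#' @return a [label_raster()].
#' @export
obc_classify <- function(segmap, scene, sigs) {
  stopifnot(inherits(sigs, "class_signature_set"))
  mu <- segment_means(segmap, scene)
  G <- discriminant_matrix(mu, sigs)
  seg_class <- sigs$class_ids[max.col(G, ties.method = "first")]
  ids <- segmap$segment_ids
  out <- matrix(0L, nrow(ids), ncol(ids))
  pos <- ids > 0L
  out[pos] <- seg_class[match(ids[pos], as.integer(rownames(mu)))]
  label_raster(out, scheme = sigs$scheme)
}
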