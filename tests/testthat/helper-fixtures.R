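# Shared fixtures and independent brute-force oracles.  Oracles are written
# from the definitions (pixel scans, direct density evaluation) and never
# call the implementation paths they check.

# published 9-class error matrices (PBC / SBC) of the IKONOS forest-cover
# study, rows = classified, columns = reference
published_pbc_matrix <- function() {
  m <- matrix(c(
    13, 13,  2,  2,  0,  1,  1,  1,  0,
     3, 25,  3,  2,  0,  1,  1,  0,  1,
     2,  6, 40,  5,  0,  3,  0,  0,  1,
     0,  0,  3, 34,  1, 10,  0,  0,  1,
     1,  1,  2,  2, 33,  5,  1,  4,  4,
     1,  1,  1,  9,  8, 27,  1,  1,  3,
     1,  2,  0,  1,  3,  3, 14,  2,  2,
     1,  1,  2,  1,  4,  5,  2, 16,  3,
     0,  1,  0,  1,  2,  1,  0,  2, 59), 9, 9, byrow = TRUE)
  error_matrix(m, default_class_scheme())
}

published_sbc_matrix <- function() {
  m <- matrix(c(
    19,  5,  0,  0,  0,  1,  0,  2,  0,
     1, 28,  0,  4,  0,  0,  0,  0,  3,
     1,  9, 44,  3,  3,  5,  0,  0,  1,
     0,  4,  7, 40,  0,  4,  1,  0,  0,
     0,  1,  0,  1, 37,  1,  0,  0,  0,
     1,  0,  2,  8,  9, 44,  0,  2,  3,
     0,  1,  0,  0,  0,  0, 18,  0,  0,
     0,  2,  0,  1,  2,  1,  0, 21,  4,
     0,  0,  0,  0,  0,  0,  1,  1, 63), 9, 9, byrow = TRUE)
  error_matrix(m, default_class_scheme())
}

# random multiband scene with uniform DNs in [lo, hi]
rand_scene <- function(H, W, B = 4, seed = 1, lo = 0, hi = 100) {
  set.seed(seed)
  multiband_scene(array(runif(H * W * B, lo, hi), c(H, W, B)))
}

# modal value of v > 0 with smallest-value tie-break; 0 when none
bf_mode_smallest <- function(v) {
  v <- v[v > 0]
  if (!length(v)) return(0L)
  tab <- table(v)
  as.integer(names(tab)[which.max(tab)])   # table names sorted numerically
}

# brute-force majority filter: truncated window, ties keep the centre class
bf_majority_filter <- function(lab, window = 3L) {
  h <- (window - 1L) / 2L
  H <- nrow(lab); W <- ncol(lab)
  out <- lab
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (lab[r, c] == 0L) next
    win <- lab[max(1, r - h):min(H, r + h), max(1, c - h):min(W, c + h)]
    win <- win[win > 0L]
    tab <- table(win)
    mx <- max(tab)
    winners <- as.integer(names(tab)[tab == mx])
    out[r, c] <- if (length(winners) > 1L) lab[r, c] else winners
  }
  out
}

# brute-force Gaussian log-discriminants via direct solve()/det()
bf_discriminants <- function(X, sigs) {
  K <- length(sigs$class_ids)
  G <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    S <- sigs$covariances[[k]]
    Si <- solve(S)
    ld <- determinant(S, logarithm = TRUE)$modulus
    for (i in seq_len(nrow(X))) {
      d <- X[i, ] - sigs$means[k, ]
      G[i, k] <- log(sigs$priors[k]) - 0.5 * ld - 0.5 * drop(t(d) %*% Si %*% d)
    }
  }
  G
}

# brute-force per-segment statistics from the pixel level
bf_segment_stats <- function(ids, scene) {
  px <- scene$pixels
  H <- nrow(ids); W <- ncol(ids); B <- dim(px)[3]
  out <- list()
  for (id in sort(unique(ids[ids > 0L]))) {
    sel <- which(ids == id, arr.ind = TRUE)
    vals <- sapply(seq_len(B), function(b) px[cbind(sel, b)])
    if (nrow(sel) == 1L) vals <- matrix(vals, 1)
    per <- 0L
    for (i in seq_len(nrow(sel))) {
      r <- sel[i, 1]; c <- sel[i, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > H || cc < 1 || cc > W || ids[rr, cc] != id)
          per <- per + 1L
      }
    }
    out[[as.character(id)]] <- segment_stats(
      n = nrow(sel), sum = colSums(vals), sumsq = colSums(vals^2),
      perimeter = per,
      bbox = c(min(sel[, 1]), max(sel[, 1]), min(sel[, 2]), max(sel[, 2])))
  }
  out
}

# shared 4-edge count between two segments of an id raster
bf_shared_edges <- function(ids, a, b) {
  H <- nrow(ids); W <- ncol(ids)
  n <- 0L
  if (H > 1) n <- n + sum((ids[-H, ] == a & ids[-1, ] == b) |
                          (ids[-H, ] == b & ids[-1, ] == a))
  if (W > 1) n <- n + sum((ids[, -W] == a & ids[, -1] == b) |
                          (ids[, -W] == b & ids[, -1] == a))
  n
}

# 4-connectivity check of every segment by flood fill
bf_all_connected <- function(ids) {
  for (id in unique(ids[ids > 0L])) {
    sel <- ids == id
    start <- which(sel, arr.ind = TRUE)[1, ]
    seen <- matrix(FALSE, nrow(ids), ncol(ids))
    stack <- list(start)
    seen[start[1], start[2]] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= nrow(ids) && c >= 1 && c <= ncol(ids) &&
            sel[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    if (!all(seen[sel])) return(FALSE)
  }
  TRUE
}

# independent per-pixel RGB -> HSI (triangle model) used as the IHS oracle
bf_rgb2hsi_px <- function(r, g, b) {
  i <- (r + g + b) / 3
  s <- if (i > 0) 1 - min(r, g, b) / i else 0
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  if (den == 0) return(c(i = i, h = 0, s = s))
  th <- acos(min(1, max(-1, 0.5 * ((r - g) + (r - b)) / den)))
  c(i = i, h = if (b <= g) th else 2 * pi - th, s = s)
}
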