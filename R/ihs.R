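#' RGB to intensity-hue-saturation conversion (triangle model)
#'
#' The triangle (hexcone) HSI model used for pan-sharpening:
#' \deqn{I = (R+G+B)/3,\qquad S = 1 - \min(R,G,B)/I,}
#' and hue is the angle
#' \deqn{\theta = \arccos\frac{\tfrac12[(R-G)+(R-B)]}{\sqrt{(R-G)^2+(R-B)(G-B)}},}
#' with \eqn{H = \theta} when \eqn{B \le G} and \eqn{H = 2\pi - \theta}
#' otherwise.  Inputs are normalized channel values in \eqn{[0,1]}.  For
#' achromatic pixels (\eqn{R=G=B}) hue is defined as 0 and saturation 0; for
#' black pixels intensity 0 and saturation 0.
#'
#' @param r,g,b numeric vectors/matrices of normalized channel values.
#' @return list with components `i`, `h` (radians in `[0, 2*pi)`), `s`.
#' @export
rgb_to_ihs <- function(r, g, b) {
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ct <- ifelse(den > 0, pmin(1, pmax(-1, num / den)), 1)
  theta <- acos(ct)
  h <- ifelse(b <= g, theta, 2 * pi - theta)
  h[den == 0] <- 0
  list(i = i, h = h, s = s)
}

#' @rdname rgb_to_ihs
#' @param i,h,s intensity, hue (radians), saturation as from [rgb_to_ihs()].
#' @return `ihs_to_rgb` returns a list with components `r`, `g`, `b`.
#' @export
ihs_to_rgb <- function(i, h, s) {
  h <- h %% (2 * pi)
  r <- g <- b <- i * 0
  third <- 2 * pi / 3
  sec1 <- h < third
  sec2 <- h >= third & h < 2 * third
  sec3 <- h >= 2 * third
  f <- function(hh) cos(hh) / cos(pi / 3 - hh)   # chroma factor within a sector
  # sector RG (0 <= H < 120 deg)
  b[sec1] <- (i * (1 - s))[sec1]
  r[sec1] <- (i * (1 + s * f(h)))[sec1]
  g[sec1] <- (3 * i)[sec1] - r[sec1] - b[sec1]
  # sector GB (120 <= H < 240)
  hh <- h - third
  r[sec2] <- (i * (1 - s))[sec2]
  g[sec2] <- (i * (1 + s * f(hh)))[sec2]
  b[sec2] <- (3 * i)[sec2] - r[sec2] - g[sec2]
  # sector BR (240 <= H < 360)
  hh <- h - 2 * third
  g[sec3] <- (i * (1 - s))[sec3]
  b[sec3] <- (i * (1 + s * f(hh)))[sec3]
  r[sec3] <- (3 * i)[sec3] - g[sec3] - b[sec3]
  list(r = r, g = g, b = b)
}

# nearest-neighbour upsampling of an H x W matrix by integer factor f
upsample_nn <- function(m, f) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f),
    drop = FALSE]
}

#' IHS pan-sharpening
#'
#' Fuses a coarse 3-band colour scene with a fine panchromatic band by
#' intensity substitution: the colour image is upsampled to the pan grid by
#' nearest neighbour, converted RGB to IHS (triangle model, see
#' [rgb_to_ihs()]), its intensity channel replaced by the pan band, and
#' converted back.  Hue and saturation of the upsampled colour image are
#' preserved exactly (to floating point) at every pixel.
#'
#' Bands of `rgb` are taken in display order red, green, blue as named in
#' `rgb$band_names` when present (any of "red"/"green"/"blue"), else bands
#' 1, 2, 3 are treated as r, g, b.
#'
#' @param rgb a 3-band [multiband_scene()] at coarse resolution.
#' @param pan a 1-band [multiband_scene()]; its dimensions must be an integer
#'   multiple of `rgb`'s.
#' @param max_dn full-scale DN used to normalize channels into `[0,1]`.
#' @return a 3-band [multiband_scene()] on the pan grid (same band order as
#'   the input `rgb`).
#' @export
ihs_pansharpen <- function(rgb, pan, max_dn = 2048) {
  stopifnot(inherits(rgb, "multiband_scene"), inherits(pan, "multiband_scene"))
  if (dim(rgb$pixels)[3] != 3L) stop("`rgb` must have exactly 3 bands")
  if (dim(pan$pixels)[3] != 1L) stop("`pan` must have exactly 1 band")
  dr <- dim(rgb$pixels); dp <- dim(pan$pixels)
  f <- dp[1] / dr[1]
  if (f != round(f) || dp[2] / dr[2] != f)
    stop("pan dimensions must be the same integer multiple of rgb dimensions")
  f <- as.integer(f)
  idx <- match(c("red", "green", "blue"), rgb$band_names)
  if (any(is.na(idx))) idx <- 1:3
  up <- lapply(idx, function(b) upsample_nn(rgb$pixels[, , b], f) / max_dn)
  ihs <- rgb_to_ihs(up[[1]], up[[2]], up[[3]])
  out <- ihs_to_rgb(pan$pixels[, , 1] / max_dn, ihs$h, ihs$s)
  px <- array(NA_real_, c(dp[1], dp[2], 3L))
  px[, , idx[1]] <- out$r * max_dn
  px[, , idx[2]] <- out$g * max_dn
  px[, , idx[3]] <- out$b * max_dn
  mask <- upsample_nn(rgb$nodata_mask, f) | pan$nodata_mask
  px[is.na(px)] <- 0
  multiband_scene(px, band_names = rgb$band_names,
                  pixel_size_m = pan$pixel_size_m, nodata_mask = mask)
}
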