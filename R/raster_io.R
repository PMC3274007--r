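#' Construct a multiband scene
#'
#' A `multiband_scene` is the working raster of the pipeline: an `H x W x B`
#' numeric array of digital numbers (DN, unitless) with band labels, a ground
#' pixel size in metres, and a nodata mask.  Pixels are addressed
#' `(row, col)` with the origin at the top-left; bands are stored in the
#' order given by `band_names`.  DNs are held as doubles internally
#' regardless of the on-disk type so that segmentation statistics are exact.
#'
#' @param pixels numeric `H x W` matrix or `H x W x B` array of digital numbers.
#' @param band_names character vector of length `B`; defaults to
#'   `c("blue","green","red","nir")` when `B == 4`, else `band1..bandB`.
#' @param pixel_size_m ground resolution of a pixel side, metres.
#' @param nodata_mask logical `H x W` matrix, `TRUE` where the cell carries no
#'   data.  Defaults to cells that are `NA` in any band.
#' @return object of class `multiband_scene` with fields `pixels`,
#'   `band_names`, `pixel_size_m`, `nodata_mask`.
#' @export
multiband_scene <- function(pixels, band_names = NULL, pixel_size_m = 1,
                            nodata_mask = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W matrix or H x W x B array")
  storage.mode(pixels) <- "double"
  d <- dim(pixels)
  if (any(d < 1L)) stop("scene dimensions must all be >= 1")
  if (is.null(band_names)) {
    band_names <- if (d[3] == 4L) c("blue", "green", "red", "nir")
                  else paste0("band", seq_len(d[3]))
  }
  if (length(band_names) != d[3])
    stop("`band_names` length must equal the number of bands")
  if (is.null(nodata_mask)) {
    nodata_mask <- apply(is.na(pixels), c(1, 2), any)
  }
  nodata_mask <- matrix(as.logical(nodata_mask), d[1], d[2])
  valid <- !nodata_mask
  if (any(!is.finite(pixels[rep(valid, d[3])])))
    stop("non-finite pixel values outside the nodata mask")
  structure(list(pixels = pixels, band_names = band_names,
                 pixel_size_m = pixel_size_m, nodata_mask = nodata_mask),
            class = "multiband_scene")
}

#' @export
print.multiband_scene <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("multiband_scene: %d x %d pixels, %d band(s) [%s], %g m/pixel, %d nodata\n",
              d[1], d[2], d[3], paste(x$band_names, collapse = ","),
              x$pixel_size_m, sum(x$nodata_mask)))
  invisible(x)
}

#' @export
dim.multiband_scene <- function(x) dim(x$pixels)

# N x B matrix of pixel vectors in column-major pixel order (including nodata
# rows, which are NA-filled where masked).
scene_band_matrix <- function(scene) {
  d <- dim(scene$pixels)
  matrix(scene$pixels, d[1] * d[2], d[3],
         dimnames = list(NULL, scene$band_names))
}

#' Construct a class scheme
#'
#' The classification legend: an ordered table of class id, abbreviation,
#' common name and large-scale group (`forest` / `non-forest`).  Ids must be
#' unique and contiguous from 1.
#'
#' @param classes data.frame with columns `id`, `abbreviation`, `common_name`,
#'   `group`.
#' @return object of class `class_scheme` (a data.frame).
#' @seealso [default_class_scheme()]
#' @export
class_scheme <- function(classes) {
  need <- c("id", "abbreviation", "common_name", "group")
  if (!all(need %in% names(classes)))
    stop("`classes` must have columns ", paste(need, collapse = ", "))
  classes <- as.data.frame(classes)[need]
  classes$id <- as.integer(classes$id)
  if (!identical(sort(classes$id), seq_len(nrow(classes))))
    stop("class ids must be unique and contiguous from 1")
  classes <- classes[order(classes$id), ]
  if (!all(classes$group %in% c("forest", "non-forest")))
    stop("`group` must be 'forest' or 'non-forest'")
  rownames(classes) <- NULL
  class(classes) <- c("class_scheme", "data.frame")
  classes
}

#' Default nine-class forest cover scheme
#'
#' Eight forest classes (seven tree species stands plus grass land) and one
#' non-forest class, the legend used for species-level forest cover mapping
#' in central Korea: pitch pine, Korean pine, Japanese larch, Mongolian oak,
#' cork oak, sawtooth oak, chestnut, grass land, and non-forest
#' (agriculture, water, built-up).
#'
#' @return a [class_scheme()] with 9 entries, ids 1..9.
#' @export
default_class_scheme <- function() {
  class_scheme(data.frame(
    id = 1:9,
    abbreviation = c("P.rig", "P.kor", "L.lep", "Q.mon", "Q.var", "Q.acu",
                     "C.cre", "grass", "nonforest"),
    common_name = c("Pitch pine", "Korean pine", "Japanese larch",
                    "Mongolian oak", "Cork oak", "Sawtooth oak", "Chestnut",
                    "Grass land", "Non-forest"),
    group = c(rep("forest", 8), "non-forest"),
    stringsAsFactors = FALSE))
}

#' Read or write a class scheme CSV
#'
#' CSV columns: `id, abbreviation, common_name, group`.
#' @param path file path.
#' @return `read_class_scheme` returns a [class_scheme()].
#' @export
read_class_scheme <- function(path) {
  class_scheme(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_class_scheme
#' @param scheme a [class_scheme()].
#' @export
write_class_scheme <- function(scheme, path) {
  write.csv(as.data.frame(scheme), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a label raster
#'
#' An `H x W` integer raster of class ids sharing the grid of a companion
#' scene; 0 is the unlabeled / nodata sentinel.  Used for training areas,
#' reference (ground-truth) maps and classified maps.
#'
#' @param labels integer `H x W` matrix; every nonzero entry must be a valid
#'   class id of `scheme`.
#' @param scheme a [class_scheme()]; default [default_class_scheme()].
#' @return object of class `label_raster` with fields `labels`, `scheme`.
#' @export
label_raster <- function(labels, scheme = default_class_scheme()) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(labels[labels != 0L]), scheme$id)
  if (length(bad))
    stop("labels contain ids outside the class scheme: ",
         paste(bad, collapse = ", "))
  structure(list(labels = labels, scheme = scheme), class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("label_raster: %d x %d, %d class(es) present, %d unlabeled\n",
              nrow(x$labels), ncol(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.label_raster <- function(x) dim(x$labels)

# ---------------------------------------------------------------------------
# File formats.
#
# "matrix" — whitespace-delimited text.  Single-band files are a bare numeric
# matrix (one raster row per line).  Multiband files carry a header line
#   # forestseg H W B <band names> pixel_size=<m>
# followed by B row-blocks of H lines.  NA marks nodata cells.  Written with
# 17 significant digits, so round-trips are bit-identical for doubles.
#
# "tif" — plain (non-geo) TIFF via the `tiff` package.  Float TIFF storage is
# defined on [0,1], so DNs are scaled by `max_dn` on write and restored on
# read; round-trips are exact to float32 precision.  Label rasters are stored
# as 16-bit integer TIFF (exact).
# ---------------------------------------------------------------------------

guess_format <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tif" else "matrix"
}

#' Read a raster file
#'
#' Reads a multiband scene from a whitespace text matrix or a TIFF file (see
#' Details in [write_raster()] for the on-disk conventions).  Cells stored as
#' `NA` (text) or equal to `nodata` (TIFF) are masked.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"matrix"` or `"tif"`.
#' @param max_dn full-scale digital number used to descale TIFF floats.
#' @param nodata optional DN value to mask on read.
#' @return a [multiband_scene()].
#' @export
read_raster <- function(path, format = c("auto", "matrix", "tif"),
                        max_dn = 2048, nodata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "matrix") {
    lines <- readLines(path)
    ps <- 1
    if (length(lines) && grepl("^# forestseg ", lines[1])) {
      hdr <- strsplit(sub("^# forestseg ", "", lines[1]), "[[:space:]]+")[[1]]
      H <- as.integer(hdr[1]); W <- as.integer(hdr[2]); B <- as.integer(hdr[3])
      bands <- hdr[seq(4, 3 + B)]
      psf <- grep("^pixel_size=", hdr, value = TRUE)
      if (length(psf)) ps <- as.numeric(sub("pixel_size=", "", psf))
      body <- lines[-1]
    } else {
      body <- lines[nzchar(lines)]
      H <- length(body); B <- 1L; bands <- NULL; W <- NA_integer_
    }
    vals <- lapply(body[nzchar(body)], function(l) {
      tok <- strsplit(trimws(l), "[[:space:]]+")[[1]]
      tok[tok == "NA"] <- NA_character_
      as.numeric(tok)
    })
    if (!length(vals)) stop("format error: empty raster file")
    if (is.na(W)) W <- length(vals[[1]])
    m <- do.call(rbind, vals)
    if (B * H != nrow(m) || ncol(m) != W)
      stop("format error: body does not match declared dimensions")
    px <- array(NA_real_, c(H, W, B))
    for (b in seq_len(B)) px[, , b] <- m[seq((b - 1) * H + 1, b * H), , drop = FALSE]
    if (!is.null(nodata)) px[!is.na(px) & px == nodata] <- NA_real_
    multiband_scene(px, band_names = bands, pixel_size_m = ps)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF I/O")
    img <- suppressWarnings(tiff::readTIFF(path, as.is = FALSE))
    if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
    if (dim(img)[3] < 1L) stop("format error: no bands in ", path)
    px <- img * max_dn
    if (!is.null(nodata)) {
      px[abs(px - nodata) < max_dn * 1e-6] <- NA_real_
    }
    multiband_scene(px)
  }
}

#' Write a raster file
#'
#' Writes a [multiband_scene()] or [label_raster()].  Text matrices are
#' lossless for doubles; TIFF stores DN/`max_dn` as 32-bit float (scenes) or
#' label/65535 as 16-bit integer (labels).  Nodata cells are written as `NA`
#' (text) or as `nodata` (TIFF scenes, default 0; labels use 0).
#'
#' @param x a [multiband_scene()] or [label_raster()].
#' @param path destination path.
#' @inheritParams read_raster
#' @param nodata DN written into masked cells of TIFF scenes.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, format = c("auto", "matrix", "tif"),
                         max_dn = 2048, nodata = 0) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (inherits(x, "label_raster"))
    return(write_label_raster(x, path, format))
  stopifnot(inherits(x, "multiband_scene"))
  d <- dim(x$pixels)
  if (format == "matrix") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# forestseg %d %d %d %s pixel_size=%.17g",
                       d[1], d[2], d[3], paste(x$band_names, collapse = " "),
                       x$pixel_size_m), con)
    for (b in seq_len(d[3])) {
      m <- x$pixels[, , b, drop = FALSE]
      dim(m) <- d[1:2]
      m[x$nodata_mask] <- NA
      writeLines(apply(m, 1, function(r)
        paste(formatC(r, digits = 17, format = "g"), collapse = " ")), con)
    }
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF I/O")
    px <- x$pixels
    for (b in seq_len(d[3])) {
      sl <- px[, , b]; sl[x$nodata_mask] <- nodata; px[, , b] <- sl
    }
    if (any(px < 0 | px > max_dn, na.rm = TRUE))
      stop("DN values outside [0, max_dn]; raise `max_dn`")
    suppressWarnings(tiff::writeTIFF(px / max_dn, path,
                                     bits.per.sample = 32L, reduce = FALSE))
  }
  invisible(path)
}

write_label_raster <- function(x, path, format) {
  if (format == "matrix") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(apply(x$labels, 1, paste, collapse = " "), con)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF I/O")
    if (max(x$labels) > 65535L) stop("label ids exceed 16-bit TIFF range")
    suppressWarnings(tiff::writeTIFF(x$labels / 65535, path,
                                     bits.per.sample = 16L, reduce = FALSE))
  }
  invisible(path)
}

#' Read a label raster
#'
#' @inheritParams read_raster
#' @param scheme a [class_scheme()] for the labels.
#' @return a [label_raster()].
#' @export
read_label_raster <- function(path, format = c("auto", "matrix", "tif"),
                              scheme = default_class_scheme()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "matrix") {
    lines <- readLines(path)
    m <- do.call(rbind, lapply(lines[nzchar(lines)], function(l)
      as.integer(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF I/O")
    img <- suppressWarnings(tiff::readTIFF(path))
    if (!is.matrix(img)) img <- img[, , 1]
    m <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  }
  label_raster(m, scheme = scheme)
}
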