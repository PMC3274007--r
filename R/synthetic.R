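#' Spectral signature of a class
#'
#' Per-class multivariate-normal model of digital numbers: a B-vector mean
#' and a B x B covariance (symmetric positive semi-definite).
#'
#' @param class_id integer class id (0 is allowed for the shadow/gap
#'   speckle signature, which belongs to no map class).
#' @param mean numeric B-vector of DN means.
#' @param covariance B x B covariance matrix.
#' @return object of class `spectral_signature`.
#' @export
spectral_signature <- function(class_id, mean, covariance) {
  covariance <- as.matrix(covariance)
  if (length(mean) != nrow(covariance) || nrow(covariance) != ncol(covariance))
    stop("mean length and covariance dimensions disagree")
  if (any(!is.finite(mean))) stop("signature mean must be finite")
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))))
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semi-definite")
  structure(list(class_id = as.integer(class_id), mean = as.numeric(mean),
                 covariance = (covariance + t(covariance)) / 2),
            class = "spectral_signature")
}

#' Default four-band signatures for the nine-class scheme
#'
#' Band order blue, green, red, NIR on an 11-bit DN scale.  The defaults
#' encode the qualitative spectral structure of early-growing-season
#' high-resolution imagery of mixed Korean forest: visible bands are only
#' modestly separated between classes, while the NIR band carries most of
#' the separation; deciduous broadleaf stands have higher NIR means than
#' coniferous stands; chestnut (C.cre), whose leaves are not fully developed
#' in early May, sits lowest among the deciduous classes; pitch pine and
#' Korean pine are nearly identical spectrally; grass land is brightest in
#' NIR and non-forest (soil, built-up, water) is bright in the visible bands
#' but low in NIR.  Within-class covariance is built from per-band standard
#' deviations with correlation 0.6 among visible bands and 0.2 between
#' visible and NIR.
#'
#' @param scheme a [class_scheme()]; signatures are returned in id order.
#' @return list of nine [spectral_signature()] objects.
#' @export
default_signatures <- function(scheme = default_class_scheme()) {
  means <- rbind(
    P.rig     = c(310, 290, 225, 430),
    P.kor     = c(313, 293, 228, 435),
    L.lep     = c(322, 308, 236, 650),
    Q.mon     = c(332, 344, 252, 1090),
    Q.var     = c(340, 352, 258, 1310),
    Q.acu     = c(335, 347, 255, 1095),
    C.cre     = c(326, 334, 246, 870),
    grass     = c(365, 400, 300, 1530),
    nonforest = c(430, 415, 405, 150))
  sds <- rbind(
    P.rig     = c(18, 18, 18, 25),
    P.kor     = c(18, 18, 18, 25),
    L.lep     = c(20, 20, 20, 28),
    Q.mon     = c(20, 22, 20, 32),
    Q.var     = c(20, 22, 20, 34),
    Q.acu     = c(20, 22, 20, 32),
    C.cre     = c(20, 22, 20, 30),
    grass     = c(22, 26, 22, 36),
    nonforest = c(36, 36, 36, 30))
  corr <- matrix(c(1.0, 0.6, 0.6, 0.2,
                   0.6, 1.0, 0.6, 0.2,
                   0.6, 0.6, 1.0, 0.2,
                   0.2, 0.2, 0.2, 1.0), 4, 4)
  lapply(scheme$id, function(i) {
    ab <- scheme$abbreviation[i]
    if (!ab %in% rownames(means))
      stop("no default signature for class ", ab)
    D <- diag(sds[ab, ])
    spectral_signature(i, means[ab, ], D %*% corr %*% D)
  })
}

# the dark shadow/gap signature used for speckle pixels
default_speckle_signature <- function() {
  sds <- c(15, 15, 15, 18)
  corr <- matrix(0.4, 4, 4); diag(corr) <- 1
  D <- diag(sds)
  spectral_signature(0L, c(110, 100, 80, 130), D %*% corr %*% D)
}

#' Synthetic scene configuration
#'
#' Parameters of the synthetic forest landscape generator.  The defaults
#' emulate the statistical structure of the mapped study landscape: a mosaic
#' of irregular stands with mean area 702 pixels (1 m pixels, i.e. 702 m^2),
#' nine cover classes, and a fraction of dark shadow/gap "speckle" pixels
#' scattered within stands that drives the salt-and-pepper effect of
#' per-pixel classification.
#'
#' @param height,width raster dimensions in pixels.
#' @param class_proportions 9-vector of expected class area shares; must be
#'   non-negative and sum to 1.
#' @param mean_stand_area_px target mean stand area in pixels (>= 25).
#' @param n_stand_seeds number of stand seeds; defaults to
#'   `round(height * width / mean_stand_area_px)`.
#' @param speckle_fraction Bernoulli probability in `[0, 1)` that a rendered
#'   pixel is replaced by a draw from the dark speckle signature.
#' @param speckle_signature [spectral_signature()] of shadow/gap pixels.
#' @param rng_seed integer seed making mosaic and rendering reproducible.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(height, width,
                         class_proportions = rep(1 / 9, 9),
                         mean_stand_area_px = 702,
                         n_stand_seeds = NULL,
                         speckle_fraction = 0.1,
                         speckle_signature = default_speckle_signature(),
                         rng_seed = 1L) {
  if (height < 1 || width < 1) stop("degenerate raster dimensions")
  if (mean_stand_area_px < 25) stop("mean_stand_area_px must be >= 25")
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must be non-negative and sum to 1")
  if (is.null(n_stand_seeds))
    n_stand_seeds <- max(1L, round(height * width / mean_stand_area_px))
  n_stand_seeds <- as.integer(n_stand_seeds)
  if (n_stand_seeds < 1) stop("degenerate config: need at least one stand seed")
  if (height * width < n_stand_seeds)
    stop("more stand seeds than pixels")
  if (speckle_fraction < 0 || speckle_fraction >= 1)
    stop("speckle_fraction must lie in [0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 class_proportions = class_proportions,
                 mean_stand_area_px = mean_stand_area_px,
                 n_stand_seeds = n_stand_seeds,
                 speckle_fraction = speckle_fraction,
                 speckle_signature = speckle_signature,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Generate a mosaic of irregular forest stands
#'
#' Seeds are dropped uniformly at random and stands grow simultaneously by
#' shortest accumulated cost over a random (exponential) pixel-cost field, a
#' seeded-region-growth construction that partitions the raster into
#' irregular, 4-connected, Voronoi-like stands.  Each seed draws its class
#' independently from `class_proportions`, so expected class area shares
#' match the proportions.  Deterministic given `config$rng_seed`.
#'
#' @param config a [scene_config()].
#' @param scheme a [class_scheme()] for the labels.
#' @return a [label_raster()] of classes 1..9 covering every pixel, with the
#'   stand partition attached as `attr(, "stand_ids")` (integer matrix,
#'   stands numbered 1..n_stand_seeds).
#' @export
generate_stand_mosaic <- function(config, scheme = default_class_scheme()) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$height; W <- config$width
  K <- length(config$class_proportions)
  if (K != nrow(scheme)) stop("class proportions do not match the scheme")
  with_seed(config$rng_seed, {
    seeds <- sample.int(H * W, config$n_stand_seeds) - 1L  # 0-based pixels
    seed_class <- sample.int(K, config$n_stand_seeds, replace = TRUE,
                             prob = config$class_proportions)
    cost <- stats::rexp(H * W) + 1e-9
    stands <- .grow_mosaic_cpp(H, W, seeds, cost)
    labels <- matrix(seed_class[stands], H, W)
    out <- label_raster(labels, scheme = scheme)
    attr(out, "stand_ids") <- stands
    out
  })
}

#' Render a stand mosaic into a multiband scene
#'
#' Each pixel is drawn from the multivariate normal of its class signature;
#' an independent Bernoulli(`speckle_fraction`) subset of pixels is then
#' replaced by draws from the dark shadow/gap signature.  Speckle pixels keep
#' their true class in the ground truth (shadows lie on real stands), so the
#' mosaic remains the reference map.  Deterministic given `config$rng_seed`.
#'
#' @param mosaic a [label_raster()] from [generate_stand_mosaic()].
#' @param signatures list of [spectral_signature()], one per class present.
#' @param config a [scene_config()].
#' @return a 4-band [multiband_scene()]; the logical speckle mask is attached
#'   as `attr(, "speckle_mask")`.
#' @export
render_scene <- function(mosaic, signatures, config) {
  stopifnot(inherits(mosaic, "label_raster"), inherits(config, "scene_config"))
  lab <- mosaic$labels
  ids <- vapply(signatures, function(s) s$class_id, integer(1))
  present <- sort(unique(as.vector(lab[lab != 0L])))
  missing <- setdiff(present, ids)
  if (length(missing))
    stop("no signature for class(es): ", paste(missing, collapse = ", "))
  B <- length(signatures[[1]]$mean)
  H <- nrow(lab); W <- ncol(lab)
  px <- matrix(NA_real_, H * W, B)
  with_seed(config$rng_seed + 1L, {
    for (cl in present) {   # fixed id order keeps the RNG stream reproducible
      sig <- signatures[[match(cl, ids)]]
      idx <- which(lab == cl)
      px[idx, ] <- MASS::mvrnorm(length(idx), sig$mean, sig$covariance)
    }
    speckle <- matrix(FALSE, H, W)
    if (config$speckle_fraction > 0) {
      speckle <- matrix(stats::runif(H * W) < config$speckle_fraction, H, W)
      speckle[lab == 0L] <- FALSE
      n_sp <- sum(speckle)
      if (n_sp > 0) {
        sp <- config$speckle_signature
        px[which(speckle), ] <- MASS::mvrnorm(n_sp, sp$mean, sp$covariance)
      }
    }
    scene <- multiband_scene(array(px, c(H, W, B)),
                             nodata_mask = lab == 0L)
    attr(scene, "speckle_mask") <- speckle
    scene
  })
}

#' Sample training areas from a stand mosaic
#'
#' Emulates visually interpreted training segments: for every class, up to
#' `n_per_class` stands with at least `min_area_px` pixels are chosen at
#' random and all their pixels labeled as training (stands are single-class
#' by construction, so every training patch lies wholly inside one class).
#' Pixels flagged in `exclude_mask` (e.g. the rendered scene's shadow/gap
#' speckle, which an interpreter would avoid) are removed from the patches.
#'
#' @param mosaic a [label_raster()] from [generate_stand_mosaic()] (must
#'   carry the `stand_ids` attribute).
#' @param n_per_class stands sampled per class.
#' @param min_area_px minimum stand area considered, in pixels.
#' @param rng_seed integer seed.
#' @param exclude_mask optional logical H x W matrix of pixels to exclude.
#' @param strict if `TRUE` (default), a class with fewer than `n_per_class`
#'   qualifying stands is an error naming the class; if `FALSE` such classes
#'   are filled as far as possible with a warning (classes entirely absent
#'   from the mosaic are skipped).
#' @return a [label_raster()] with training pixels labeled and 0 elsewhere.
#' @export
sample_training_areas <- function(mosaic, n_per_class = 2, min_area_px = 25,
                                  rng_seed = 1L, exclude_mask = NULL,
                                  strict = TRUE) {
  stopifnot(inherits(mosaic, "label_raster"))
  stands <- attr(mosaic, "stand_ids")
  if (is.null(stands)) stop("mosaic lacks the 'stand_ids' attribute")
  lab <- mosaic$labels
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (n_per_class >= 1) {
    sizes <- tabulate(stands)
    first_px <- match(seq_along(sizes), as.vector(stands))
    stand_class <- lab[first_px]
    with_seed(rng_seed, {
      for (cl in mosaic$scheme$id) {
        cand <- which(stand_class == cl & sizes >= min_area_px)
        if (length(cand) < n_per_class) {
          msg <- sprintf(
            "class %s: only %d stand(s) of >= %d px available (need %d)",
            mosaic$scheme$abbreviation[cl], length(cand), min_area_px,
            n_per_class)
          if (strict) stop("training sampling failed; ", msg)
          if (length(cand) == 0) next
          warning("partial training sample; ", msg)
        }
        take <- if (length(cand) == 1) cand
                else sample(cand, min(n_per_class, length(cand)))
        out[stands %in% take] <- cl
      }
    })
  }
  if (!is.null(exclude_mask)) out[exclude_mask] <- 0L
  label_raster(out, scheme = mosaic$scheme)
}

#' Simulate a complete synthetic forest scene
#'
#' Convenience wrapper chaining [scene_config()], [generate_stand_mosaic()],
#' [render_scene()] and [sample_training_areas()], returning everything the
#' classification pipeline needs: the rendered scene, the ground-truth
#' reference map, and a shadow-free training raster.
#'
#' @inheritParams scene_config
#' @param n_training_stands stands sampled per class for training (classes
#'   absent from the mosaic are skipped with a warning).
#' @param signatures list of [spectral_signature()]; default
#'   [default_signatures()].
#' @param scheme a [class_scheme()].
#' @return list with elements `scene` ([multiband_scene()]), `reference`
#'   ([label_raster()] ground truth), `training` ([label_raster()]),
#'   `config`, `signatures`, and `speckle_mask`.
#' @export
simulate_forest_scene <- function(height = 128, width = 128,
                                  speckle_fraction = 0.1,
                                  rng_seed = 1L,
                                  n_training_stands = 2,
                                  signatures = default_signatures(),
                                  scheme = default_class_scheme(), ...) {
  cfg <- scene_config(height, width, speckle_fraction = speckle_fraction,
                      rng_seed = rng_seed, ...)
  mosaic <- generate_stand_mosaic(cfg, scheme = scheme)
  scene <- render_scene(mosaic, signatures, cfg)
  speckle <- attr(scene, "speckle_mask")
  training <- suppressWarnings(
    sample_training_areas(mosaic, n_per_class = n_training_stands,
                          min_area_px = 25, rng_seed = rng_seed + 2L,
                          exclude_mask = speckle, strict = FALSE))
  list(scene = scene, reference = mosaic, training = training,
       config = cfg, signatures = signatures, speckle_mask = speckle)
}
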