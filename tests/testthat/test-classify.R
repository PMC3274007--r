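# tiny labelled scene: two horizontal bands of classes 1 and 2 plus a
# training raster marking a few pixels of each
two_class_fixture <- function(seed = 1, sd1 = 1, sd2 = 1) {
  set.seed(seed)
  px <- array(NA_real_, c(6, 6, 2))
  px[1:3, , 1] <- rnorm(18, 10, sd1); px[1:3, , 2] <- rnorm(18, 10, sd1)
  px[4:6, , 1] <- rnorm(18, 30, sd2); px[4:6, , 2] <- rnorm(18, 30, sd2)
  sc <- multiband_scene(px)
  tr <- matrix(0L, 6, 6)
  tr[1:3, 1:3] <- 1L; tr[4:6, 1:3] <- 2L
  list(scene = sc, training = label_raster(tr))
}

test_that("signature estimation matches the textbook formulas", {
  fx <- two_class_fixture(3)
  sigs <- extract_signatures(fx$scene, fx$training, "equal")
  X <- matrix(fx$scene$pixels, 36, 2)
  for (k in 1:2) {
    sel <- as.vector(fx$training$labels) == k
    expect_equal(sigs$means[k, ], colMeans(X[sel, ]), ignore_attr = TRUE)
    expect_equal(sigs$covariances[[k]], cov(X[sel, ]), ignore_attr = TRUE)
    expect_equal(sigs$n_training[k], 9L, ignore_attr = TRUE)
  }
  expect_equal(sigs$priors, c(0.5, 0.5))
})

test_that("proportional priors follow the training counts", {
  set.seed(4)
  sc <- multiband_scene(array(rnorm(200 * 1 * 2), c(200, 1, 2)))
  tr <- matrix(0L, 200, 1)
  tr[1:50] <- 1L; tr[51:200] <- 2L
  sigs <- extract_signatures(sc, label_raster(tr), "proportional")
  expect_equal(sigs$priors, c(0.25, 0.75))
})

test_that("degenerate training sets are flagged or rejected", {
  px <- array(5, c(4, 4, 2))
  sc <- multiband_scene(px)
  tr <- matrix(0L, 4, 4); tr[1, 1:2] <- 1L
  expect_warning(sigs <- extract_signatures(sc, label_raster(tr)),
                 "below B \\+ 1")
  # constant training: zero covariance, regularized discriminant still works
  expect_equal(sigs$means[1, ], c(5, 5), ignore_attr = TRUE)
  expect_equal(unname(sigs$covariances[[1]]), matrix(0, 2, 2))
  out <- ml_classify(sc, sigs)
  expect_true(all(out$labels == 1L))

  tr2 <- matrix(0L, 4, 4); tr2[1, 1] <- 1L
  expect_error(extract_signatures(sc, label_raster(tr2)), "P.rig")
})

test_that("maximum likelihood reduces to nearest mean for identity covariances", {
  sigs <- structure(list(
    class_ids = c(1L, 2L),
    means = rbind(c(0, 0), c(10, 10)),
    covariances = list(diag(2), diag(2)),
    n_training = c(10L, 10L), priors = c(0.5, 0.5),
    band_names = c("b1", "b2"), scheme = default_class_scheme()),
    class = "class_signature_set")
  sc <- multiband_scene(array(1, c(1, 1, 2)))
  expect_equal(as.vector(ml_classify(sc, sigs)$labels), 1L)
  sc2 <- multiband_scene(array(6, c(1, 1, 2)))
  expect_equal(as.vector(ml_classify(sc2, sigs)$labels), 2L)
})

test_that("ml_classify matches brute-force density evaluation with full covariances", {
  set.seed(9)
  B <- 3
  mk <- function() { A <- matrix(rnorm(B * B), B); crossprod(A) + diag(B) }
  sigs <- structure(list(
    class_ids = 1:3,
    means = rbind(rnorm(B, 0), rnorm(B, 2), rnorm(B, 4)),
    covariances = list(mk(), mk(), mk()),
    n_training = c(20L, 20L, 20L), priors = c(0.2, 0.5, 0.3),
    band_names = paste0("b", 1:B), scheme = default_class_scheme()),
    class = "class_signature_set")
  X <- matrix(rnorm(50 * B, 2, 3), 50, B)
  sc <- multiband_scene(array(X, c(50, 1, B)))
  got <- as.vector(ml_classify(sc, sigs)$labels)
  G <- bf_discriminants(X, sigs)
  expect_equal(got, max.col(G, ties.method = "first"))
})

test_that("classification is invariant to rescaling all priors", {
  fx <- two_class_fixture(11, sd1 = 3, sd2 = 3)
  sigs <- extract_signatures(fx$scene, fx$training)
  sigs2 <- sigs
  sigs2$priors <- sigs$priors * 7   # common factor shifts every g_i equally
  expect_identical(ml_classify(fx$scene, sigs)$labels,
                   ml_classify(fx$scene, sigs2)$labels)
})

test_that("nodata pixels classify to 0", {
  fx <- two_class_fixture(5)
  px <- fx$scene$pixels
  mask <- matrix(FALSE, 6, 6); mask[2, 2] <- TRUE
  sc <- multiband_scene(px, nodata_mask = mask)
  sigs <- extract_signatures(sc, fx$training)
  out <- ml_classify(sc, sigs)
  expect_equal(out$labels[2, 2], 0L)
  expect_true(all(out$labels[!mask] > 0L))
})

test_that("majority filter smooths salt-and-pepper and honours the tie rule", {
  lab <- matrix(1L, 5, 5)
  expect_identical(majority_filter(label_raster(lab))$labels, lab)

  lab2 <- lab; lab2[3, 3] <- 2L    # isolated inclusion vanishes
  expect_identical(majority_filter(label_raster(lab2))$labels, lab)

  set.seed(13)
  lab3 <- matrix(sample(1:4, 100, TRUE), 10, 10)
  expect_identical(majority_filter(label_raster(lab3), 3L)$labels,
                   bf_majority_filter(lab3, 3L))
  expect_identical(majority_filter(label_raster(lab3), 5L)$labels,
                   bf_majority_filter(lab3, 5L))
  expect_error(majority_filter(label_raster(lab3), 4L), "odd")
})

test_that("majority filter never invents a class missing from the window", {
  set.seed(17)
  lab <- matrix(sample(c(1L, 3L, 7L), 64, TRUE), 8, 8)
  out <- majority_filter(label_raster(lab))$labels
  for (r in 1:8) for (c in 1:8) {
    win <- lab[max(1, r - 1):min(8, r + 1), max(1, c - 1):min(8, c + 1)]
    expect_true(out[r, c] %in% win)
  }
})

test_that("object-based classification agrees with the discriminant on means", {
  sim <- simulate_forest_scene(48, 48, speckle_fraction = 0.05, rng_seed = 3)
  sigs <- extract_signatures(sim$scene, sim$training)
  # with single-pixel segments OBC reduces to the pixel classifier
  seg0 <- init_segments(sim$scene)
  expect_identical(obc_classify(seg0, sim$scene, sigs)$labels,
                   ml_classify(sim$scene, sigs)$labels)
  # with real segments each segment takes the class of its mean vector
  seg <- segment_scene(sim$scene, segmentation_params(80, 0.5, 0.5), 1)
  out <- obc_classify(seg, sim$scene, sigs)
  mu <- segment_means(seg, sim$scene)
  G <- bf_discriminants(mu, sigs)
  want <- sigs$class_ids[max.col(G, ties.method = "first")]
  for (i in seq_len(nrow(mu))) {
    id <- as.integer(rownames(mu))[i]
    expect_equal(unique(out$labels[seg$segment_ids == id]), want[i])
  }
})

test_that("a pure zero-noise stand classifies to its own class", {
  sig <- default_signatures()[[4]]
  cfg <- scene_config(30, 30, n_stand_seeds = 1, speckle_fraction = 0,
                      rng_seed = 2)
  mos <- generate_stand_mosaic(cfg)
  mos$labels[] <- 4L
  flat <- lapply(default_signatures(), function(s)
    spectral_signature(s$class_id, s$mean, diag(1e-4, 4)))
  scene <- render_scene(mos, flat, cfg)
  sigs <- extract_signatures(scene,
            label_raster(matrix(4L, 30, 30)))
  seg <- segment_scene(scene, segmentation_params(30, 1), 1)
  expect_equal(n_segments(seg), 1L)
  expect_true(all(obc_classify(seg, scene, sigs)$labels == 4L))
})
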