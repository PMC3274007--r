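#' Parse a segmentation case label
#'
#' Decodes the compact `C_S(M O)` weight notation used for segmentation
#' experiments, e.g. `"C9S1(M9O1)"`: C = colour, S = shape, M = smoothness,
#' O = compactness, with subscripts 1 = 0.1, 3 = 0.25, 5 = 0.5, 7 = 0.75 and
#' 9 = 0.9.  Colour and shape weights must be complementary (sum to 1), as
#' must smoothness and compactness.
#'
#' @param label case string matching `C<d>S<d>(M<d>O<d>)`.
#' @return object of class `sweep_case`: list with `label` and `params`
#'   (a [segmentation_params()] carrying the weights; its scale is a
#'   placeholder replaced cell by cell during a sweep).
#' @export
parse_case_label <- function(label) {
  m <- regmatches(label,
                  regexec("^C([13579])S([13579])\\(M([13579])O([13579])\\)$",
                          label))[[1]]
  if (length(m) != 5)
    stop("malformed case label (expected C<d>S<d>(M<d>O<d>)): ", label)
  code <- c(`1` = 0.1, `3` = 0.25, `5` = 0.5, `7` = 0.75, `9` = 0.9)
  w <- code[m[2:5]]
  if (abs(w[1] + w[2] - 1) > 1e-9)
    stop("colour and shape weights must sum to 1 in ", label)
  if (abs(w[3] + w[4] - 1) > 1e-9)
    stop("smoothness and compactness weights must sum to 1 in ", label)
  structure(list(label = label,
                 params = segmentation_params(scale = 1, w_color = w[[1]],
                                              w_compact = w[[4]])),
            class = "sweep_case")
}

#' The nine standard weight cases
#'
#' The step I-III design exploring extreme (0.1/0.9), average (0.5) and
#' intermediate (0.25/0.75) colour and shape weights.
#'
#' @return list of [parse_case_label()] results.
#' @export
standard_sweep_cases <- function() {
  lapply(c("C9S1(M9O1)", "C9S1(M1O9)", "C1S9(M9O1)", "C1S9(M1O9)",
           "C5S5(M5O5)", "C5S5(M9O1)", "C5S5(M1O9)",
           "C7S3(M5O5)", "C3S7(M5O5)"),
         parse_case_label)
}

#' Run the segmentation-scale experiment
#'
#' For every (case, scale) cell: segment the scene, reclassify the
#' pixel-based map by segment majority (SBC), and score it.  The pixel-based
#' map (PBC), its 3x3 majority-filtered version, and an object-based
#' classification (OBC, on the segments of `baseline_case` at
#' `baseline_scale`) are scored once with the same test units, giving the
#' standard four-method comparison.
#'
#' Two assessment modes are available.  `"clusters"` mirrors the field
#' protocol: one shared sample of homogeneous 9x9 test windows is scored by
#' modal class, so all comparisons are paired.  `"pixels"` scores every
#' valid pixel against the full reference map ([pixel_error_matrix()]) --
#' the natural choice on simulated scenes, where complete ground truth is
#' available and per-pixel effects such as the salt-and-pepper error are
#' measured directly rather than through 81-pixel modal votes.
#'
#' @param scene a [multiband_scene()].
#' @param training a [label_raster()] of training areas.
#' @param reference a [label_raster()] ground truth for accuracy assessment.
#' @param cases list of `sweep_case` objects (see [parse_case_label()]).
#' @param scales numeric vector of scale parameters (default 30 to 280 in
#'   steps of 20).
#' @param rng_seed integer seed driving segmentation visiting order and
#'   cluster sampling.
#' @param prior_mode passed to [extract_signatures()].
#' @param baseline_case,baseline_scale segmentation used for the OBC
#'   baseline.
#' @param assessment `"clusters"` (field protocol) or `"pixels"` (full-map).
#' @param cluster_half_width test-window half width (default 4: 9x9).
#' @param test_base,test_floor passed to [allocate_test_counts()].
#' @param verbose log progress to stderr.
#' @return data.frame of class `sweep_result`: columns `method` (PBC,
#'   majority3, OBC or SBC), `case_label`, `scale`, `n_segments`,
#'   `overall_accuracy`, `kappa`.  A failed cell yields an NA row with a
#'   warning rather than aborting the sweep.
#' @export
run_sweep <- function(scene, training, reference, cases = standard_sweep_cases(),
                      scales = seq(30, 280, by = 20), rng_seed = 1L,
                      prior_mode = "equal",
                      baseline_case = "C5S5(M5O5)", baseline_scale = 160,
                      assessment = c("clusters", "pixels"),
                      cluster_half_width = 4L, test_base = 50, test_floor = 5,
                      verbose = FALSE) {
  assessment <- match.arg(assessment)
  if (!length(cases) || any(scales <= 0)) stop("invalid cases or scales")
  if (inherits(cases, "sweep_case")) cases <- list(cases)
  say <- function(...) if (verbose) message(sprintf(...))
  sigs <- extract_signatures(scene, training, prior_mode)
  pbc <- ml_classify(scene, sigs)
  if (assessment == "clusters") {
    alloc <- allocate_test_counts(reference, base = test_base,
                                  floor = test_floor)
    clusters <- suppressWarnings(
      sample_test_clusters(reference, alloc, half_width = cluster_half_width,
                           rng_seed = rng_seed, strict = FALSE))
    say("sampled %d test clusters", nrow(clusters))
    score <- function(labmap) {
      m <- build_error_matrix(labmap, clusters, reference$scheme)
      c(overall_accuracy(m), kappa_statistic(m))
    }
  } else {
    clusters <- NULL
    score <- function(labmap) {
      m <- pixel_error_matrix(labmap, reference)
      c(overall_accuracy(m), kappa_statistic(m))
    }
  }
  rows <- list()
  add <- function(method, case_label, scale, nseg, sc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, case_label = case_label, scale = scale,
      n_segments = nseg, overall_accuracy = sc[1], kappa = sc[2],
      stringsAsFactors = FALSE)
  }
  add("PBC", NA_character_, NA_real_, NA_integer_, score(pbc))
  add("majority3", NA_character_, NA_real_, NA_integer_,
      score(majority_filter(pbc, 3L)))
  base_params <- parse_case_label(baseline_case)$params
  base_params$scale <- baseline_scale
  obc_seg <- segment_scene(scene, base_params, rng_seed)
  add("OBC", baseline_case, baseline_scale, n_segments(obc_seg),
      score(obc_classify(obc_seg, scene, sigs)))
  for (cs in cases) {
    for (s in scales) {
      res <- tryCatch({
        p <- cs$params
        p$scale <- s
        seg <- segment_scene(scene, p, rng_seed)
        sbc <- segment_majority(pbc, seg)
        list(nseg = n_segments(seg), sc = score(sbc))
      }, error = function(e) {
        warning(sprintf("cell %s scale %g failed: %s", cs$label, s,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(res)) add("SBC", cs$label, s, NA_integer_, c(NA, NA))
      else add("SBC", cs$label, s, res$nseg, res$sc)
      say("case %s scale %g: %s", cs$label, s,
          if (is.null(res)) "failed" else sprintf("%d segments, kappa %.3f",
                                                  res$nseg, res$sc[2]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "clusters") <- clusters
  out
}

#' Find the kappa plateau of a sweep
#'
#' Returns the SBC sweep cells whose kappa lies within `tolerance` of the
#' maximum, i.e. the (case, scale) region where segmentation is effectively
#' optimal.
#'
#' @param result a `sweep_result` from [run_sweep()] (or any data.frame with
#'   `method`, `case_label`, `scale`, `kappa`).
#' @param tolerance allowed kappa drop from the maximum (default 0.02).
#' @return data.frame of the plateau cells, ordered by decreasing kappa.
#' @export
find_plateau <- function(result, tolerance = 0.02) {
  if (!nrow(result)) stop("empty sweep result")
  sbc <- result[result$method == "SBC" & !is.na(result$kappa), , drop = FALSE]
  if (!nrow(sbc)) sbc <- result[!is.na(result$kappa), , drop = FALSE]
  if (!nrow(sbc)) stop("no finite kappa values in the result")
  best <- max(sbc$kappa)
  out <- sbc[sbc$kappa >= best - tolerance, , drop = FALSE]
  out[order(-out$kappa), ]
}
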