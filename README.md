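# forestseg

Species-level forest cover mapping from high-resolution multiband imagery:
multiresolution region-growing **segmentation**, Gaussian maximum-likelihood
**pixel-based classification** (PBC), **segment-based classification** (SBC)
by majority rule, the standard comparison baselines (3×3 majority filter,
object-based classification on segment means), and error-matrix / kappa
**accuracy assessment** — plus a synthetic forest-landscape simulator so the
whole pipeline runs against known ground truth.

Per-pixel maximum-likelihood classification of metre-resolution forest
imagery produces the *salt-and-pepper effect*: crown shadows and canopy gaps
scatter isolated misclassified pixels through otherwise homogeneous stands.
SBC repairs this by first partitioning the image into spectrally homogeneous
objects and then reassigning every pixel of each object to the plurality PBC
class inside it.

## The model in brief

Segmentation merges objects while the heterogeneity gain stays below
`scale²`:

```
Δh_color = Σ_b w_b [ n_m σ_b(m) − n_a σ_b(a) − n_b σ_b(b) ]
h_cmp    = l/√n          h_smooth = l/b_bbox
cost     = w_color Δh_color + (1 − w_color) [ w_cmp Δh_cmp + (1 − w_cmp) Δh_smooth ]
```

with σ the population standard deviation per band, `l` the exposed-edge
perimeter and `b_bbox` the bounding-box perimeter.  Weight cases use the
compact `C5S5(M5O5)` notation (subscripts 1/3/5/7/9 ↦ 0.1/0.25/0.5/0.75/0.9).
Classification is the Gaussian discriminant
`g_i(x) = ln p_i − ½ln|Σ_i| − ½(x−μ_i)ᵀΣ_i⁻¹(x−μ_i)`; accuracy is
summarized by overall accuracy `trace(M)/N` and Cohen's kappa
`κ = (p_o − p_e)/(1 − p_e)` over an error matrix of classified (rows) ×
reference (columns) test units.

## Worked example

```r
library(forestseg)

# published 9-class SBC error matrix bundled with the package
m <- read_error_matrix(system.file("extdata", "error_matrix_sbc.csv",
                                   package = "forestseg"))
sprintf("SBC: overall %.1f%%, kappa %.3f",
        100 * overall_accuracy(m), kappa_statistic(m))
#> "SBC: overall 76.8%, kappa 0.734"

# simulate a 128x128 forest landscape (mean stand 702 px, 10% shadow/gap
# speckle), then sweep the C5S5(M5O5) case over three scales
sim <- simulate_forest_scene(128, 128, speckle_fraction = 0.1, rng_seed = 1)
res <- run_sweep(sim$scene, sim$training, sim$reference,
                 cases = parse_case_label("C5S5(M5O5)"),
                 scales = c(60, 90, 120), rng_seed = 1,
                 assessment = "pixels")
res[, c("method", "scale", "n_segments", "overall_accuracy", "kappa")]
#>      method scale n_segments overall_accuracy kappa
#> 1       PBC    NA         NA            0.810 0.772
#> 2 majority3    NA         NA            0.864 0.839
#> 3       OBC   160         11            0.705 0.650
#> 4       SBC    60        758            0.795 0.758
#> 5       SBC    90        315            0.796 0.761
#> 6       SBC   120         13            0.819 0.788
```

`overall_accuracy` here is pixel-wise against the simulated ground truth;
`n_segments` shows objects growing with scale.  A single scene is noisy —
averaged over eight seeds (what `scripts/acceptance.R` prints) the methods
separate cleanly: SBC ≈ 84.7% at the detected plateau scale, 3×3 majority
filter ≈ 81.7%, PBC ≈ 73.9%, OBC ≈ 65.4%, and at scale 240 the colour-heavy
case C9S1(M9O1) holds κ ≈ 0.70 while shape-heavy C1S9(M9O1) drops to
κ ≈ 0.37.

A command-line front end with `simulate` / `segment` / `classify` / `sbc` /
`assess` / `sweep` subcommands ships at `inst/cli/forestseg.R`:

```sh
Rscript inst/cli/forestseg.R simulate --height 128 --width 128 --seed 3 --out-dir run
Rscript inst/cli/forestseg.R sweep --scene run/scene.txt --training run/training.txt \
        --reference run/reference.txt --scales 30:280:20 --mode pixels --out-dir run
```

## Layout

* `R/`, `src/` — pipeline implementation (segmentation core in C++).
* `inst/extdata/` — nine-class scheme; published PBC/SBC error matrices.
* `vignettes/forest-cover-mapping.Rmd` — the methods vignette: model,
  assumptions, generator design, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests with brute-force
  oracles.
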