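# histoseg

Segmentation of grayscale medical images — brain MRI slices with
hyperintense (e.g. ischemic-stroke) lesions in particular — by
**histogram-analysis mixture modeling coupled to a deformable model**.

Classical deformable models stop the evolving contour with an edge term,
`g = 1 / (1 + |∇G_σ∗I|²)`, which fails on the weak, partial-volume
boundaries that lesions typically present. `histoseg` instead:

1. fits a Gaussian mixture `ρ(x) = Σ_l π_l N(x; μ_l, σ_l²)` to the image
   intensity histogram by expectation–maximization (exact weighted
   likelihood on the binned histogram, log-space E-step, canonical
   ascending-mean component order, BIC selection of the component count);
2. replaces the gradient stop term with the mixture's posterior statistics:
   the contour speed is the posterior log-odds
   `F(x) = log Σ_{l∈obj} π_l N(x;μ_l,σ_l²) − log Σ_{l∉obj} π_l N(x;μ_l,σ_l²)`,
   positive exactly where the object components win;
3. evolves a level set under `∂φ/∂t = −F|∇φ| + ν κ|∇φ|` with upwind
   differencing, a CFL guard, and periodic signed-distance
   reinitialization, yielding the object mask `{φ < 0}`.

Classical parametric-snake (PD) and geodesic-active-contour (GD) baselines,
voxel metrics (sensitivity, specificity, overall performance, Dice),
rank-based ROC/AUC, a seeded brain-like phantom generator with exact ground
truth, NIfTI/PNG I/O and a command-line interface are included, so the whole
pipeline is testable without clinical data. See the vignette in
`vignettes/histogram-mixture-segmentation.Rmd` for the model, numerics and
design decisions.

## Worked example

```r
library(histoseg)

# brain-like phantom: background/parenchyma/lesion at (20, 110, 200),
# additive Gaussian noise sd 9
ph <- generate_phantom(phantom_spec(shape = c(96, 96), noise_sigma = 9,
                                    seed = 42))

fit <- fit_gmm_em(build_histogram(ph$image), L = 3)
fit
#> <gmm_fit> L = 3, 12 iterations, converged (logL = -41218.4810)
#>   component      pi     mu sigma2
#> 1         1 0.44347  19.75  81.83
#> 2         2 0.50868 109.98  82.35
#> 3         3 0.04785 200.57  80.91

res <- segment(ph$image, L = 3, object_rule = "brightest")
res
#> <segmentation_result> 96 x 96, object pixels = 441, 100 iterations, converged

eq7_metrics(confusion_from_masks(res$mask, ph$truth_mask))
#>   sensitivity specificity overall_performance dice
#> 1           1           1                   1    1
```

The fit recovers the three generating class means (20, 110, 200) to within
a fraction of the noise level, with the lesion component correctly small
(π ≈ 0.048), and the posterior-speed contour reproduces the ground-truth
lesion mask exactly on this image: all 441 lesion pixels and no others.

`compare_methods_suite()` runs the proposed method against the GD and PD
baselines over a seeded weak-edge phantom suite with a shared
region-of-interest initialization and reports per-image Dice.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "histoseg", package = "histoseg")`, with subcommands
`simulate`, `fit-gmm`, `segment` (`--method proposed|gd|pd`), `evaluate`
and `roc`.

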