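---
title: "Histogram-analysis mixture segmentation with deformable models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-analysis mixture segmentation with deformable models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoseg)
```

## The problem

Ischemic-stroke lesions appear on some MRI sequences (FLAIR, DWI) as
hyperintense regions whose borders are often blurred by partial-volume
averaging and perilesional edema. Classical deformable-model segmentation
stops the evolving contour with an *edge* term — a decreasing function of the
smoothed image gradient — and therefore leaks through exactly the weak,
low-gradient boundaries that stroke lesions present. `histoseg` implements
the alternative this package is organized around: estimate the image's
global intensity structure from its histogram with a Gaussian mixture model
(GMM), and let the *posterior statistics* of that mixture, not the local
gradient, drive and stop the contour.

## The intensity mixture and its EM fit

The intensity histogram is modeled as a univariate mixture of $L$ Gaussian
components,

$$\rho(x) = \sum_{l=1}^{L} \pi_l \, \mathcal{N}(x;\, \mu_l, \sigma_l^2),
\qquad \sum_l \pi_l = 1,\; 0 \le \pi_l \le 1 .$$

The model is univariate by design: the object of analysis is the histogram
of one image (or one sequence), so each component's covariance is a scalar
variance. Fitting is maximum likelihood by expectation–maximization. The
E-step computes responsibilities

$$r_{il} = \frac{\pi_l\,\mathcal{N}(x_i;\mu_l,\sigma^2_l)}
               {\sum_k \pi_k\,\mathcal{N}(x_i;\mu_k,\sigma^2_k)},$$

evaluated in log space (log-sum-exp), so far-tail samples never underflow to
a division by zero. The M-step is the canonical responsibility-weighted
update

$$\pi_l \leftarrow \tfrac{1}{M}\textstyle\sum_i w_i r_{il},\qquad
\mu_l \leftarrow \frac{\sum_i w_i r_{il} x_i}{\sum_i w_i r_{il}},\qquad
\sigma^2_l \leftarrow \frac{\sum_i w_i r_{il}\,(x_i-\mu_l)^2}{\sum_i w_i r_{il}},$$

with weights $w_i$ so that a binned histogram (bin centers as values, counts
as weights) is fitted by *exact* weighted likelihood rather than approximate
resampling. Each iteration's log-likelihood
$K = \sum_i w_i \log \rho(x_i)$ is recorded; the trace is guaranteed
nondecreasing and the tests assert it with $10^{-8}$ slack.

Numerical guards, each chosen once and used everywhere:

* **Convergence** — relative log-likelihood change below `tol` ($10^{-6}$ by
  default) or 500 iterations. Cheap, standard, testable.
* **Variance floor** — $10^{-6} \times (\text{data range})^2$, the classical
  guard against a component collapsing onto a single intensity. A component
  whose effective count vanishes is reseeded at the sample the mixture
  currently explains worst, with a logged message, never a crash.
* **Canonical order** — components are sorted by ascending mean, so "the
  brightest component" is a stable notion across runs and seeds.

### Initialization

Initialization matters more than usual here because brain histograms are
extremely unbalanced: a lesion may hold 2–5 % of the pixels at the far
bright end. Mass-based quantile initialization places all starting means
inside the two big modes and EM then often absorbs the lesion into a broad
parenchyma component. The default `init_method = "range"` therefore spaces
the starting means evenly between the 1st and 99th intensity percentiles,
guaranteeing the bright tail a nearby component. `"quantile"`, `"kmeans"`
and `"random"` remain available, and `"best"` runs EM from the three
deterministic initializations and keeps the highest-likelihood fit — the
recommended setting when histograms are heavily blurred.

### Choosing $L$

No single component count is right for every image: three classes
(background, parenchyma, lesion) suffice for sharp images, while
partial-volume ramps effectively add a fourth population. `select_components()`
fits every candidate and scores each by BIC, $-2\log L + (3L-1)\log M$, with
ties broken toward the smaller model; the comparison harness selects $L$
per image over 2–5.

## From mixture to moving contour

The contour is an implicit level set $\phi$ (negative inside the object).
Where a classical geometric model uses the edge-stopping factor
$g = 1/(1+|\nabla G_\sigma * I|^2)$, the proposed model replaces it with the
posterior log-odds of the object components:

$$F(x) = \log\!\!\sum_{l \in \text{obj}}\!\! \pi_l\,\mathcal{N}(x;\mu_l,\sigma^2_l)
       \;-\; \log\!\!\sum_{l \notin \text{obj}}\!\! \pi_l\,\mathcal{N}(x;\mu_l,\sigma^2_l),$$

clipped to $[-10, 10]$. $F$ is positive exactly where the object posterior
wins, so the contour expands over object-like intensities and retreats from
background-like ones regardless of how shallow the local gradient is. This
log-posterior-ratio speed is the canonical way to turn mixture statistics
into a curve-evolution force (it reduces to region competition); the method
is implemented purely region-driven, with the edge-driven variant available
as the geodesic baseline rather than blended in.

Evolution uses explicit Euler steps of
$\partial_t\phi = -F\,|\nabla\phi|_{\text{upwind}} + \nu\,\kappa\,|\nabla\phi|$
with Osher–Sethian upwind gradients, a central-difference curvature $\kappa$
(clipped to $[-1,1]$, the stable range of the stencil), and a CFL guard
$dt \cdot \max|F| \le 0.5$ that raises a configuration error rather than
silently destabilizing; the end-to-end `segment()` wrapper instead rescales
the speed into the stable range. Every `reinit_every = 10` iterations the
field is reinitialized to a signed distance function via the Euclidean
distance transform, and convergence is judged *between* those checkpoints:
the fraction of pixels whose sign changed per iteration must fall below
`convergence_frac` ($10^{-4}$). Judging between checkpoints matters because
at sub-pixel speeds a single iteration flips no signs even while the front
is moving steadily. Updates are restricted to a narrow band
($|\phi| \le 6$ by default). Three-dimensional volumes are processed
slice-wise along the third axis, matching how such lesions are read on 2-D
slices; full 3-D stencils are a non-goal.

## Baselines

Two classical deformable baselines make the comparison concrete:

* **PD (parametric)** — a Kass-style snake: a closed control-point polygon
  under internal tension ($\alpha_s$) and bending ($\beta_s$) forces plus an
  external force pulling toward intensity edges, iterated with the implicit
  pentadiagonal update and resampled to equal arc length every 10 iterations
  to stay simple.
* **GD (geometric)** — a geodesic active contour:
  $\partial_t\phi = g(-c|\nabla\phi| + \nu\kappa|\nabla\phi|) + \nabla g \cdot \nabla\phi$
  with a constant balloon force $c$ ($c>0$ expands, $c<0$ contracts).

The cited model families do not pin down specific published variants;
these canonical members are implemented because the comparison needs the
*families'* characteristic behavior — edge-dependence — not any particular
paper's tuning.

## The phantom generator

`generate_phantom()` emulates what makes this segmentation problem hard
while keeping ground truth exact: a dark background, an elliptical
parenchyma "brain", and an elliptical or blob-shaped lesion, painted at
class means (20, 110, 200) on a [0, 255] scale so the default resembles a
FLAIR-hyperintense lesion; additive Gaussian noise; an optional smooth
multiplicative second-order polynomial bias field (the simplest realistic
MRI inhomogeneity that breaks pure histogram separability); and an optional
Gaussian blur of the class image *before* noise, which produces the shallow
partial-volume edges the weak-edge suite is built from. The label map is
recorded before blur and noise, so truth is exact by construction and every
output is a pure function of spec + seed.

`phantom_suite()` draws per-image geometry and class means from fixed
ranges at three difficulties — `crisp` (noise sd 2), `weak-edge` (blur sd
2.5–3.5 px, noise sd 6) and `noisy` (noise at 20 % of the smallest class
contrast) — with per-image seeds derived from one master seed.

What the generator does **not** model: Rician noise statistics, intra-class
texture, multi-sequence contrast, motion or susceptibility artifacts, or
anatomy beyond one brain-like ellipse. Passing the phantom suites therefore
demonstrates correctness of the estimation and evolution machinery and the
claimed edge-robustness ordering, not clinical-grade performance on patient
data.

## The comparison protocol

`compare_methods_suite()` runs all three methods over a seeded suite with
identical, truth-derived initialization: a generous region of interest (the
lesion bounding box dilated by 6 px; the snake starts on the circumscribed
circle), mimicking an operator seeding an ROI. Sharing the initialization
isolates what the comparison is about — the stopping force. The proposed
method selects $L$ by BIC with multi-start EM; the GD baseline contracts
($c = -1$) from the same ROI. On weak-edge suites the test suite asserts the
mean-Dice ordering proposed ≥ GD and proposed ≥ PD.

Problem sizes throughout the tests and the acceptance script — 64×64
phantoms, 20-image suites, $10^4$-sample recovery runs — are the package's
own choice of smallest sizes at which the statistical claims are stable.

## Known limitations

* Purely intensity-driven: spatially overlapping intensity distributions
  (strong bias fields, lesions isointense with another tissue) are
  indistinguishable at the histogram level; no Markov-random-field or atlas
  prior is included (a stated non-goal).
* Single object class per run (two-phase level set); multi-phase evolution
  is a non-goal.
* The snake baseline's rasterization is even-odd scanline on the final
  polygon; self-intersections are prevented only by periodic resampling.
* PNG output is written at 8 bits (16-bit PNG is read exactly but the
  underlying writer is 8-bit); NIfTI round-trips losslessly and preserves
  the source header.
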