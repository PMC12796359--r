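---
title: "Quantifying lymph-node microvasculature with super-resolution ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lymph-node microvasculature with super-resolution ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srusq)
```

## The problem

Distinguishing metastatic from reactive (benign, enlarged) cervical lymph
nodes is a routine and consequential task in head-and-neck oncology.
Conventional ultrasound is diffraction-limited to roughly 200 µm and cannot
resolve the microvascular remodelling — angiogenic vessel sprouting, tortuous
branching, chaotic flow — that accompanies nodal metastasis. Super-resolution
ultrasound (SRUS, also called ultrasound localization microscopy) breaks that
limit by localizing individual intravascular microbubbles across thousands of
contrast-enhanced frames and accumulating their positions and motions into
maps with ~10 µm scale detail.

`srusq` implements a complete, testable version of that analysis chain:

1. **Simulation** — synthetic vascular phantoms with *reactive* and
   *metastatic* phenotypes, microbubble track sets under the clinical
   acquisition geometry (500 frames/s for 6 s, 3000 frames, whole-node ROI),
   and a copula-based generator of cohort-level parameter tables calibrated
   to published group statistics.
2. **Map building** — localized tracks accumulated into density, intensity,
   velocity and direction grids at a 25 µm pixel pitch, with 1-second
   time-resolved segment maps and a 0.5 mm inter-frame motion gate.
3. **Quantification** — fourteen per-node parameters (below).
4. **Diagnostics** — group comparison, univariate ROC with DeLong variance,
   and forward-conditional stepwise logistic modelling of metastatic status.

Because no patient data are distributed, the synthetic generators are
first-class, tested components: they define the study conditions under which
every statistical claim in the test suite is evaluated.

## The fourteen parameters

For a map set restricted to the node ROI (every grid congruent, pixels of
size $h$ µm), with vascular mask $V$ = pixels inside the ROI holding at least
one localization (the threshold is configurable via `quant_config()`):

| Parameter | Definition | Units |
|---|---|---|
| VD | $|V| / |\mathrm{ROI}|$ | fraction |
| Dmax, Dmean, Dstd | max / mean / SD of local diameters $(2d-1)h$ at skeleton pixels, $d$ = Euclidean distance to background | µm |
| FWVD | $\sum_{p \in V} I_p / |\mathrm{ROI}|$ | intensity / pixel |
| FD | box-counting slope of $\log N(s)$ vs $\log 1/s$, clamped to $[0,2]$ | — |
| Vmean, Vmax, Vmin | statistics of per-pixel mean speed over $V$ with flow signal | mm/s |
| Vel Var | population variance of those speeds | (mm/s)² |
| Vel Entropy | Shannon entropy of the $K$-bin speed histogram over $(0, \max]$, divided by $\ln K$ | $[0,1]$ |
| Dir Var | mean squared deviation (wrapped to $[-180,180)$) of per-pixel directions about their circular mean | deg² |
| Dir Entropy | normalized entropy of the $K$-bin angular histogram over $[-180,180)$ | $[0,1]$ |
| PI | $V_{mean} \times VD$ (exact identity) | mm/s |

Numerical conventions that the reported definitions leave open, fixed here
once:

* **Vascular pixel rule.** A pixel is vascular if it received ≥ 1
  localization. The threshold is a `quant_config()` field because real
  pipelines sometimes require 2–3 localizations to suppress false
  detections.
* **Entropy normalization.** Both entropies are divided by $\ln K$
  (default $K = 64$) so they live in $[0,1]$; published values in the
  0.6–0.95 range are consistent with this scale, while raw-nat entropies
  would exceed 1.
* **Velocity histogram range.** Anchored at $(0, \text{per-node max}]$, so
  a node's entropy does not depend on other nodes in the batch.
* **Vmin excludes background.** Pixels with no flow signal (no track step)
  are undefined, not zero; published minimum velocities of ~2.6 mm/s imply
  zeros were not counted.
* **Dir Var in degrees squared.** Deviations are taken about the circular
  mean and wrapped, then averaged linearly; a uniform direction
  distribution gives 10800 deg² in expectation, matching the ~4400 deg²
  mid-range of published values (a unit-circle circular variance, bounded
  by 1, could not).
* **Diameters.** Skeleton (Zhang–Suen thinning) + Euclidean distance
  transform with the $2d-1$ correction is the standard morphometric
  estimator; it is validated against analytic strip widths in the tests.
* **FD fit range.** Box sizes are powers of two up to half the smaller grid
  dimension; the smallest and largest sizes are dropped from the log–log
  fit when at least four sizes exist, avoiding saturation bias at the scale
  extremes. Validated against a filled square (2), a line (1), and a
  depth-6 Sierpinski raster ($\log 3/\log 2 \approx 1.585$).
* **Map accumulation.** Per-pixel velocity is the arithmetic mean of
  contributing track-step speeds (finite difference × frame rate,
  gap-aware); direction is the circular mean of step unit vectors, because
  naive angle averaging breaks at the ±180° wrap. Each step is binned at
  the pixel of its starting localization.
* **Grid convention.** Image convention (x right, y down), pixel-centre
  registration; the mm ↔ pixel mapping round-trips to within half a pixel.

## The synthetic phantoms

`phantom_config()` exposes two presets constrained by the qualitative
contrast the imaging literature reports — reactive nodes show organized,
hilum-centred vasculature with uniform flow; metastatic nodes show denser,
tortuous networks entered from all around the capsule with chaotic flow.
Specific constants (branching probability, tortuosity, radius decay,
velocity heterogeneity) are invented, documented plumbing: nothing published
pins them down, and only the *direction* of the metastatic − reactive
contrast is treated as a testable claim.

Design choices that required iteration, recorded here because they are easy
to get wrong:

* **Per-branch speed heterogeneity.** Branch flow speeds are drawn
  independently per branch (bounded log-normal factor around
  `velocity_mean`), not inherited down a tree, so a single node carries the
  full within-node speed distribution and node-level summaries are stable.
* **Chaotic-perfusion mixture.** A fraction `1.8 * (velocity_cv - 0.1)` of
  branches draw their speed uniformly over
  `[velocity_floor, 2.2 * velocity_mean]`. Without this component a
  "heterogeneous" phenotype built from skewed log-normal tails actually has
  *lower* velocity entropy than an organized one (its own maximum stretches
  the histogram range and concentrates the bulk in few bins); uniform
  spread is what makes flow chaotic in the entropy sense.
* **Generation slowdown saturates.** The per-generation speed decay stops
  compounding at depth 3 (a capillary plateau); unbounded compounding made
  even organized networks broad-spectrum.
* **Localization noise.** Default 5 µm sd (~10–12 µm FWHM spot, the SRUS
  resolution scale). At 500 frames/s, localization noise enters apparent
  step speeds as $\sqrt{2}\,\sigma f$; pessimistic values (25 µm) swamp the
  biological velocity contrast entirely.
* **Simulation is 2-D** (one imaging plane), matching the clinical
  acquisition; no 3-D phantoms.

What the phantom path does *not* emulate: point-spread-function overlap and
localization failures, bubble disruption, vessel occlusion by attenuation,
out-of-plane flow, and the vendor's proprietary tracker (a minimal greedy
nearest-neighbour linker is provided as a pluggable stand-in). Passing tests
on this path show the estimators are correct and the qualitative phenotype
contrast survives a realistic acquisition — not that the simulator
reproduces clinical images.

## The calibrated cohort generator

Published cohort-level results report per-group mean ± SD for each of the 14
parameters (77 metastatic, 89 reactive nodes), but not the joint
distribution. `cohort_calibration()` therefore samples from a Gaussian
copula:

1. Draw correlated standard normals from a shared 14 × 14 correlation
   matrix (shipped as `inst/extdata/default_correlation.csv`).
2. Push each margin through a quantile transform so that its *observed*
   (post-truncation) mean and SD equal the published values.

Margins default to normals truncated to physical ranges (VD and entropies in
$[0,1]$, FD in $[0,2]$, velocities and variances ≥ 0, Dir Var ≤ 180² deg²).
Two published margins are infeasible for a truncated normal — a mean of
0.922 with SD 0.092 on $[0,1]$ exceeds the family's dispersion limit near a
bound (the exponential-tail supremum is ≈ 0.078), and a half-line margin
with SD > mean (reactive minimum velocity, 2.645 ± 2.800) cannot arise from
a normal truncated at 0. For such margins the calibration switches to a
two-moment-matched Beta (finite bounds) or Gamma (half-line), so every
margin reproduces its published mean *and* SD exactly in expectation. The
moment solver (`tnorm_match_moments()`) is constrained to a numerically safe
region (≥ 1e-8 parent mass inside the bounds) because the truncated-normal
moment formulas silently lose precision in the far-tail limit.

The correlation matrix itself is under-determined by the marginals. It
encodes a domain-plausible block structure — morphology (VD, FWVD, FD,
diameters), velocity (Vmean, Vmax, Vmin, Vel Var, Vel Entropy), direction
(Dir Var, Dir Entropy), and perfusion couplings (PI with VD and Vmean) — and
was calibrated once so that the five-predictor diagnostic model (VD, Vmin,
Vel Var, Vel Entropy, PI) attains its published in-sample discrimination
(AUC ≈ 0.81) on cohorts of the published size, then frozen. The skew of real
parameter distributions beyond mean ± SD is unknowable from the published
summaries; the large reactive-group SDs hint at skew that the generator
represents only through truncation and the Beta/Gamma fallbacks.

## The statistics pipeline

```{r stats, eval = FALSE}
co <- generate_cohort(cohort_calibration(), seed = 1)
compare_groups(co)                  # normality-gated t / Mann-Whitney table
univariate_roc(co, "DirEntropy")    # empirical AUC, DeLong CI, Youden point
pp <- preprocess_cohort(co)         # VD x100; FD/entropies/DirVar/FWVD z-scored
m  <- stepwise_logistic(pp$design, pp$labels)
m$spec <- pp$spec
evaluate_model(m, co)               # combined-model ROC
```

Choices where the reported methods leave latitude:

* **Welch t-test** rather than pooled-variance, behind the per-group
  Shapiro–Wilk gate at α = 0.05 (the normality rule is stated, the test is
  not; Welch is the safer default).
* **Entry/removal tests are likelihood-ratio tests** (entry p < 0.05,
  removal p > 0.10). The originating software's "forward conditional"
  method uses score entry and conditional-LR removal whose exact internals
  are not reproducible from public documentation; LR tests are a deliberate
  near-equivalent, and the full selection trace is recorded.
* **Youden ties** resolve toward the higher-specificity threshold.
* **OR confidence intervals** are Wald intervals on the log-odds scale;
  `OR = exp(beta)` holds to machine precision by construction.
* **ROC direction** defaults to "larger value ⇒ metastatic" without
  direction-correction, so inverse markers (e.g. minimum velocity) can show
  AUC < 0.5, mirroring how such tables are usually printed;
  `direction = "auto"` flips them.
* **Preprocessing follows the published footnote literally**: VD enters as
  a percentage (×100); FD, Vel Entropy, Dir Entropy, Dir Var and FWVD are
  Z-standardized (cohort means/SDs stored for scoring new data). The
  footnote's marking is internally inconsistent (one variable carries both
  marks; another's odds-ratio magnitude suggests standardization but is
  unmarked); the footnote text is applied as written rather than silently
  "fixed". AUCs are invariant to these affine transforms in any case.
* **Stepwise false entries.** With entry α = 0.05 and $k$ pure-noise
  candidates, forward selection admits a spurious variable in roughly
  $1-(1-\alpha)^k$ of replicates; that is a property of the procedure, not
  a defect, and the tests bound it rather than pretending exact recovery.

## Problem sizes and determinism

Default problem sizes were chosen so that a complete run is desk-scale: the
800 × 800 map grid (20 mm field of view at 25 µm) quantifies in a few
seconds per node; marginal calibration checks use 10⁵ samples per group
(Monte-Carlo SE ≈ SD/316); model-discrimination checks average 200
replicate cohorts of the published 77/89 size. Every random stage consumes a
named substream derived from one user seed (phantom / tracks / motion /
cohort), so `run_pipeline()` reproduces byte-identical numeric report blocks
under a fixed seed, and library calls never disturb the caller's RNG state.

## Known limitations

* The phantom path and the cohort path are calibrated to different surfaces
  (image-level estimator correctness vs cohort-level statistics); per-node
  parameters computed from simulated images are *not* calibrated to the
  published per-group magnitudes (e.g. density-map VD depends on bubble
  count and acquisition length), only to their ordering between phenotypes.
* The tracker is a greedy nearest-neighbour linker; it is adequate for
  sparse simulated bubbles and exercised by tests, but it is not a
  production multi-target tracker.
* Diameter estimates are quantized by the pixel pitch; sub-pixel vessel
  widths are reported at ≥ 1 pixel.
* 2-D only; bi-directional flow maps and per-vessel graph extraction are
  out of scope.
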