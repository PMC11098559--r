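---
title: "Models and methods behind myostates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myostates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myostates)
```

# The kinetic model

A loaded Mant-ATP chase reports the nucleotide turnover of resting myosin:
fluorescent Mant-ATP bound to myosin heads is chased with dark ATP, and the
fiber fluorescence decays as heads release their labelled nucleotide. After
background subtraction and normalization to the final pre-washout frame
(t = 0), the decay is modelled as

$$F(t) = 1 - P_1\,(1 - e^{-t/T_1}) - P_2\,(1 - e^{-t/T_2}),$$

with the faster component (amplitude $P_1$, lifetime $T_1$) attributed to
the disordered-relaxed state (DRX) and the slower one ($P_2$, $T_2$) to the
super-relaxed state (SRX). $1 - P_1 - P_2$ is a non-exchanging plateau,
allowed to be positive because the fit is intentionally unconstrained in
that respect. The model equals 1 at $t = 0$ for any parameters, which is
asserted symbolically in the test suite.

Assumptions worth keeping in mind:

* two exchanging populations with single-exponential kinetics each — no
  distributed lifetimes, no triple-exponential component, no
  photobleaching correction;
* the three sampled fiber regions are averaged *before* fitting (one fit
  per fiber), matching the background-subtract-then-average convention;
  per-ROI fitting is available via `extract_roi_traces()` on individual
  masks;
* additive, homoscedastic Gaussian noise on the normalized scale.

## Fitting: multi-start profiled least squares

The model is linear in $(P_1, P_2)$ once $(T_1, T_2)$ are fixed, so the
optimizer profiles the amplitudes out by a closed-form 2×2 normal-equation
solve and searches only over log-lifetimes. A 3×3 multi-start grid
($T_1 \in \{2, 10, 30\}$ s × $T_2 \in \{100, 200, 400\}$ s) makes the
search robust to local optima; the best start by residual sum of squares
wins. All four parameters are then polished by Levenberg–Marquardt
(`minpack.lm::nlsLM`) with relative tolerances of $10^{-10}$ and up to
10 000 evaluations, which also supplies curvature-based standard errors.

Numerical choices:

* **Constraints.** The default refinement uses loose boxes (amplitude
  fractions in $[-0.1, 1.2]$, lifetimes in $[0.1, 5000]$ s). This keeps
  noisy traces away from pathological optima while leaving the intended
  "unconstrained" behaviour intact in practice; `fit_options(unconstrained
  = TRUE)` removes the boxes entirely.
* **Labelling.** Components are relabelled after fitting so the faster
  lifetime is always reported as (P1, T1) = DRX. The assignment never
  depends on start ordering (tested by permuting the start grids), and is
  never swapped afterwards.
* **Degeneracy.** Near-collinear lifetime bases fall back to a single
  component inside the profiling step. Fits whose lifetimes differ by less
  than 5× with overlapping 95% intervals are flagged `LIFETIMES_CLOSE`;
  amplitudes below 1% raise `DEGENERATE_COMPONENT`; amplitude sums above
  100% raise `AMPLITUDE_SUM_GT_100` (the fiber is kept — the flag makes
  the condition visible downstream). Non-convergence yields
  `converged = FALSE` with absent parameters rather than silent numbers.

## Identifiability of T1 on a 5-second grid

With frames every 5 s over 300 s and noise of sd 0.01 on the normalized
scale, a fast lifetime of ~15 s is sampled by only a handful of points. The
test suite computes the Cramér–Rao bound at the canonical truth
(P1 = 25%, T1 = 15 s, P2 = 50%, T2 = 200 s): the relative standard error of
an efficient unbiased estimator is ≈ 6% for P1, ≈ 10% for T1, ≈ 3% for P2
and ≈ 12% for T2. The fitter's replicate errors sit essentially on that
bound, so residual scatter in T1 at these settings reflects the information
content of the acquisition grid, not the optimizer. Recovery tests
therefore assert efficiency relative to the bound rather than an arbitrary
constant.

# Energetics

Per-fiber resting ATP consumption assumes 220 µM myosin heads within the
fiber volume (an assumption, exposed as `head_concentration_uM`):
$(P_1/100)\cdot C\cdot(60/T_1) + (P_2/100)\cdot C\cdot(60/T_2)$, in
µM·min⁻¹. Temperature sensitivity is summarised per matched animal — the
ratio of the animal's mean T1, T2 and ATP consumption at the warm vs cold
assay temperature — not over pooled fibers, because animals are the
experimental unit. Percent differences are always reported as signed
change versus a named baseline group (a "35% lower" value is −35).

# Group statistics

Fiber-level values are aggregated to unweighted animal means per
condition × fiber type × temperature, and all group tests run on those
means. The one-way ANOVA is the classical equal-variance F test; a Welch
variant can be obtained directly from `stats::oneway.test` if desired. The
two-way ANOVA uses type-II sums of squares, a standard choice for mildly
unbalanced layouts that coincides with the classical decomposition when
balanced; pairwise follow-ups use pooled t-tests with Šídák adjustment
$p' = 1 - (1-p)^m$ over the family of pairs. No multiplicity correction is
applied *across* the many fiber-type × metric one-way ANOVAs — each is
reported at face value, and reports state the baseline and family
explicitly. For the PTM analysis the default two-way factors are site ×
condition.

# X-ray reflection quantification

Profiles live in detector space (radius in mm); spacings use the exact
Bragg relation $\theta = \tfrac12\arctan(r/L)$, $d = \lambda/(2\sin\theta)$
with λ = 0.10 nm and L = 2.14 m by default. At this geometry the
small-angle approximation $d \approx \lambda L / r$ deviates by
$\sim\tfrac{3}{8}(r/L)^2$ — about 0.01% at d ≈ 6 nm — which is why the
exact form is used throughout.

Background is removed by an iterated polynomial under-fit (fit, clip
points above the fit, refit; degree 4, 30 passes by default), or a
linear-under-peak variant inside a window; the method is configurable
because published reductions vary. Negative residuals are preserved and
flagged, never clipped. Each reflection is then fit as a Gaussian plus
local linear baseline by Levenberg–Marquardt inside a search window
(defaults: d ≈ 14.34 nm for M3 and 7.17 nm for M6, ±5%); windows should
comfortably contain the peak — several Gaussian widths — or the
peak/baseline decomposition becomes ill-posed. "Intensity" means
integrated Gaussian area (standard for reflection intensities; peak height
is also reported). A window with no peak above five times the local noise
scale errors with `NOPEAK` rather than returning a fit. Cross-exposure
intensity comparisons use a per-profile total-intensity normalization
(`intensity_norm`), a stated convention rather than a universal standard.

# Proteomics statistics

Preprocessing follows the common left-censored missingness treatment:
log2 transform, exclusion of features with fewer than two valid values in
*any* group (the strict reading of the filter), then MinProb-style
imputation drawing each missing cell from a per-sample Gaussian with mean
= sample mean − 1.8 × sample SD and SD = 0.3 × sample SD, under a caller
seed so imputation is reproducible. Differential expression uses per-feature
unpaired t-tests — Welch by default for robustness, pooled optionally —
with Benjamini–Hochberg FDR, and calls significance only when FDR < 0.05
*and* the linear fold-change exceeds 2. Zero-variance features get a
variance floor and a `VAR_FLOOR` flag instead of an NaN. PTM-site z-scores
standardize each site across *all* samples (mean 0, unit SD), then average
per condition; positive condition means are called hyper-modified.
Within-condition-block standardization is a defensible alternative; the
across-samples choice makes the condition means directly comparable on one
scale. Sample PCA is centered (optionally scaled) `prcomp`.

# The synthetic-data module

The generator is the package's study stand-in, not a convenience fixture.
Its defaults encode the study conditions the analysis expects:

* 3 conditions (SA/IBA/torpor) or any subset, 5 animals per condition,
  8–12 fibers per animal, 50/50 type I/II (configurable — real fiber-type
  proportions are species- and muscle-dependent);
* acquisition every 5 s for 300 s; baseline decay truth (25%, 15 s, 50%,
  200 s) for both fiber types;
* condition effects as multiplicative lifetime factors and additive DRX
  amplitude shifts per fiber type, with lognormal between-animal (CV
  0.075) and within-animal (CV 0.15) lifetime variability and Gaussian
  amplitude scatter (SD 0.015 animal, 0.03 fiber) — magnitudes chosen once
  to mirror the visual spread of published per-fiber scatter plots, where
  fibers scatter widely but animal means are comparatively tight;
* additive Gaussian noise of sd 0.01 on the normalized decay (published
  decays are visually smooth), a drawn baseline intensity (400–800 a.u.)
  and background level (20–80 a.u.) so background subtraction and
  normalization are non-trivial; optional linear background drift is off
  by default;
* invalid hierarchical draws (e.g. amplitude sums above 1) are resampled,
  so every emitted truth satisfies the model invariants;
* image stacks place the raw trace value in three disjoint fiber ROIs over
  a background level, with optional Gaussian pixel noise — ROI averaging
  reproduces the tabular trace exactly at zero noise;
* diffraction profiles place Gaussian peaks at the exact Bragg radius on a
  smooth monotone background; abundance matrices are log-normal with a
  designated DE fraction and logistic left-censored missingness.

What the generator does **not** emulate: photobleaching, fiber movement or
focus drift, detector nonlinearity, correlated (non-white) noise,
fiber-type misclassification, peptide-level quantification noise shared
across PTM sites, and batch effects. Passing tests therefore demonstrate
correctness of the estimators under the stated stochastic model, not
robustness to every artefact of real recordings.

# Problem sizes and determinism

The shipped tests and the reproduction script use deliberately compact
problem sizes — 100–200 replicate fibers for recovery distributions, 100
simulated two-condition studies (5 animals × 10 fibers) for end-to-end
effect recovery, 10 000 null simulations for ANOVA calibration, 50
synthetic matrices for FDR control, 100 random synthetic reflections for
spacing recovery — sizes at which the Monte-Carlo error is small relative
to the asserted margins. Every stochastic step is seeded; the pipeline
writes a manifest of md5 file hashes, and re-running with the same config
and seed reproduces the hashes exactly.

# Known limitations

* T1 precision is bounded by the 5-s acquisition grid (see above);
  experiments targeting fast DRX kinetics would need denser early frames.
* The Welch-vs-pooled t-test default may differ from other pipelines'
  choices; both are available, and calls near the significance boundary
  can differ between them.
* The imputation follows the downshifted-Gaussian convention for MinProb
  with width 0.3 and shift 1.8; other tools' exact random generators may
  differ in detail even with identical parameters.
* Reflections are modelled as Gaussians on local linear baselines; heavily
  overlapping reflections or strongly curved local backgrounds are out of
  scope, as is reduction of 2D detector images to 1D profiles.
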