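---
title: "afidqc: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{afidqc: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afidqc)
```

# The error model

All coordinates live in RAS+ world millimeters; files in the LPS dialect
are converted at the I/O boundary and nowhere else. A *fiducial set* is a
labeled collection of 3D points for one subject, rater and space; labels
are mapped to the 32-landmark protocol registry, and unmatched labels
(electrode tips, ad-hoc points) are kept with id 0 rather than rejected.

Three error metrics share one table layout (signed or unsigned per-axis
components in mm plus the Euclidean norm, tagged by kind):

* **LD** — pairwise inter-rater distance. Axis components are *unsigned*
  (absolute differences), matching how per-axis LD is conventionally
  reported.
* **AFLE** — rater minus consensus, where a consensus is the
  component-wise mean of at least three independent raters. Consensus
  from fewer raters is refused unless explicitly overridden, because
  "error" against a two-rater mean is misleading.
* **AFRE** — transformed landmark minus template consensus, *signed*,
  because the downstream covariance analyses need direction. Global AFRE
  is the per-subject mean of Euclidean AFRE over available landmarks.
  Missing landmarks are dropped pairwise, never imputed.

Nonlinear warps are dense displacement fields: a voxel grid of world-mm
3-vectors with a voxel-to-world affine, sampled by trilinear
interpolation at continuous 0-based voxel coordinates. A transform chain
applies affine steps as `p ↦ M p` and field steps as `p ↦ p + D(p)`. The
chain maps *subject-space points to template space*; whether the on-disk
field of a given registration package is the forward or inverse warp for
points is the caller's responsibility, because packages genuinely differ
(a field suitable for resampling images is typically the inverse of the
point map). Out-of-bounds sampling raises an error naming the point; a
clamp-to-edge mode is opt-in, since silent extrapolation quietly corrupts
AFRE.

# The attribution analysis

Electrode tips are centered by subtracting the mean tip position per side
(left/right electrodes are not mirrored), then pooled, so 24 subjects
contribute 48 electrodes. Three views connect tip displacement to AFRE:

1. **r² map** — for each landmark and Cartesian axis, a simple regression
   of the tip component on the same-axis signed AFRE component across
   electrodes, with two significance tiers (`p < 0.05` and `p < 0.05/32`).
   A subject's AFRE row is paired with both of that subject's electrodes,
   since both share one registration.
2. **Correlation matrices** — pairwise r² between landmark components in
   Cartesian axes, or with each landmark's AFRE first projected onto its
   own principal components.
3. **Stacked PCA and attribution** — covariance PCA of the subjects × 3k
   matrix of signed AFRE components of k landmarks (default landmarks 2,
   3, 4, 14: PC, infracollicular sulcus, pontomedullary junction, pineal
   gland — midline structures near the STN). Tip displacements get their
   own 3-feature PCA. Every AFRE component score (top 4) is regressed on
   every tip component score; the PrC1-on-PrC1 cell is the headline:
   its r² is the explained fraction of tip variance along the dominant
   axis, and `explained_mm = |slope × AFRE-PrC1 score|` converts it to
   per-electrode millimeters. That reading of "millimeters explained" (the
   absolute fitted values of the PrC1 regression) is a declared choice;
   the quantity is reported with median and min–max range.

PCA is always covariance PCA (features share mm units; no
standardization), implemented as the eigendecomposition of the sample
covariance after column centering. Component signs are fixed by making
each component's largest-magnitude loading positive — correlations are
sign-invariant, but scores and plots need determinism.

# The synthetic cohort

The generator formalizes the structure the analysis assumes. For subject
k with latent score `s_k ~ N(0, σ_s²)`:

```
fiducial j:  F_jk = T_j + s_k Φ(T_j) + R_k(T_j) + η_jk
tip (side):  X_k  = E   + s_k Φ(E)   + R_k(E)   + δ_k
```

* `Φ` — the shared misregistration pattern, a fixed sum of Gaussian bumps
  `Σ_b a_b exp(−‖p − c_b‖²/2w_b²)`. Defaults: two midline bumps near the
  midbrain (centers (0,−20,−8) and (0,−32,−15) mm, widths 20/18 mm) with
  dominantly anteroposterior amplitudes (≈0.9 and 0.6 mm in y), so the
  pattern is identical at the mirrored electrode targets and strongest at
  midline subcortical landmarks — the spatial signature the analysis is
  meant to detect. Pattern magnitude at the target is ≈1.1 mm.
* `R_k` — an independent smooth residual field per subject: 12 fresh
  Gaussian bumps (width 15 mm, centers uniform over a brain-sized box,
  amplitudes N(0, 0.5²) mm per axis). Smooth rather than iid noise,
  because real misregistration is spatially correlated; its per-axis
  variance at any point has a closed form (an erf-product integral over
  the center distribution), ≈0.1 mm² near the target.
* `η` — iid per-axis rater localization noise, σ_loc = 0.4 mm,
  consistent with sub-voxel (≈0.7 mm Euclidean) inter-rater distances on
  clinical images.
* `δ_k` — iid per-axis surgical deviation, σ_app = 1.5 mm by default,
  making tip displacement ≈2.5 mm Euclidean — surgical variability
  dominating registration, as observed cohorts show.
* Electrode target (12, −13, −7) mm and its x-mirror: a plausible STN
  pair.

Cohorts are bit-reproducible from (spec, seed) and prefix-stable (random
draws are consumed strictly subject by subject). `simulate_cohort`
returns full ground truth: scores, pattern values, residual values at the
targets, and the planted surgical deviations.

**What a green test does not establish.** The generator emulates the
*statistical* structure only: no images, no brain shift or
pneumocephalus, no rater bias fields, no left–right asymmetry of the
pattern, Gaussian everything, and a single dominant latent score (a
multi-pattern option exists through extra bump sets, but the default is
rank-1 in subject space). Passing recovery tests shows the estimator
chain is correct under this idealization, not that any particular
clinical cohort behaves this way.

## The analytic expected r²

`theoretical_r2()` is the population value of the attribution statistic
under the model. The joint covariance of the 3k stacked AFRE features and
the 3 tip axes is assembled in closed form — the rank-one pattern term
`σ_s² φ φᵀ`, the residual kernel covariance between any two evaluation
points (an erf-product with an `exp(−‖p−q‖²/4w²)` separation factor), and
the diagonal localization/surgical terms — and the statistic is evaluated
on the leading eigenvectors `u_a`, `u_t` of the two marginal blocks:

```
r² = (u_aᵀ S_at u_t)² / (u_aᵀ S_aa u_a)(u_tᵀ S_tt u_t)
```

A simpler first-order reading, `σ_s²‖Φ(E)‖² / (σ_s²‖Φ(E)‖² + Var R(E) +
σ_app²)`, ignores two real effects the full form captures: attenuation
from estimating the latent score through noisy fiducials (the AFRE-side
noise along `u_a`), and residual-field covariance shared between
fiducials and target. At the defaults these shift the expected r² by
roughly 4% relative — enough to matter against a ±0.05 recovery band.
The full form was verified against empirical covariance blocks of an
n = 4000 simulated cohort. A spec whose pattern vanishes at the target is
degenerate by contract and returns 0.

`calibrate_surgical_sd()` inverts the map analytically (monotone
root-finding on σ_app), so "a cohort with expected r² = 0.28" is a
stated, closed-form construction — never a quantity tuned against
simulation output.

Even with the exact population target, the n = 500 *estimator* is not
unbiased: sample principal axes wobble, attenuating the measured r² by
about 0.013, with a per-seed sd near 0.02. The recovery acceptance test
therefore checks the ensemble mean over 20 seeded cohorts against the
planted value within ±0.05 (and bounds each seed at twice that band);
demanding every individual seed land within ±0.05 would fail about half
the time by order statistics alone, independent of implementation
quality.

# Numerical conventions

* **Quartiles** — linear interpolation between order statistics
  (`quantile type 7`). Published cohort IQRs do not state their method;
  this choice is documented so small IQR mismatches are explainable, not
  fitted.
* **Variance** — n−1 denominator. **RMSE** — root of the mean square of
  signed per-axis errors; the identity
  `mean(Euclidean²) = Σ_axis RMSE_axis²` reconciles axiswise-RMSE
  reporting with Euclidean summaries and is asserted in the tests.
* **Wilcoxon policy** — zero differences dropped, mid-ranks for ties,
  exact null distribution when the effective n ≤ 25 (a shift-algorithm
  DP on doubled ranks, so half-integer mid-ranks stay exact), otherwise
  a normal approximation with tie correction and continuity correction;
  two-sided p = min(1, 2·min(tails)). `stats::wilcox.test` refuses
  exactness under ties, which is why the tests pin this policy against
  exhaustive enumeration oracles instead.
* **Bonferroni** — both tiers are always reported (nominal α and α/m,
  m = 32 for per-landmark families, 6 for axis families), mirroring
  `*`/`**` heatmap annotation.
* **Trilinear sampling** — exact for fields affine in world position
  (asserted at 1e-9), making the interpolator testable without
  tolerance-tuning.
* **Rounding for presentation** — half away from zero at 2 decimals;
  raw doubles are always available. The analytic VTA radius of a 100 mm³
  sphere is 2.8794 mm → 2.88; the source publication prints 2.89, which
  its own Dice values (0.74/0.50/0.29, all reproduced exactly) are only
  consistent with at r = 2.8794. The corresponding acceptance assertion
  is deliberately left failing rather than adjusted.
* **Configuration** — JSON only (`jsonlite`); no YAML parser is part of
  the supported dependency footprint.
* **CSV/JSON outputs** — printed at fixed precision so re-runs are
  byte-identical.

# Limitations

* Only equal-radius sphere overlap is implemented; unequal radii are
  rejected explicitly rather than silently generalized.
* No spatial interpolation of AFRE to arbitrary coordinates, no
  cross-validation of the attribution, and no clinical-outcome modeling.
* Image registration itself, image resampling, warp inversion and
  composite-transform containers (HDF5) are out of scope: export a dense
  field first.
* The registry's anatomical descriptions for landmarks not used in any
  computation are informational and editable
  (`inst/extdata/afid_protocol.json`); the bundled full-template
  coordinate file is a synthetic stand-in except for the two published
  consensus points (AC, PC), and is labeled as such.
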