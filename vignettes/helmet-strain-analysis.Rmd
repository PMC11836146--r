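---
title: "Tract-related brain strain and kinematic injury metrics for helmet impact ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-related brain strain and kinematic injury metrics for helmet impact ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helmstrain)
library(dplyr)
```

## The analysis in one paragraph

Oblique helmet drop tests produce, for each helmet and impact location, a
30 ms record of head centre-of-gravity kinematics: three axes of linear
acceleration (g) and angular velocity (rad/s) in a headform-fixed frame,
sampled every 0.05 ms (600 samples). These records feed two assessment
layers: *kinematic* injury metrics computed directly from the curves, and
*tissue-level* strain metrics post-processed from per-element
deformation-gradient histories of a finite-element-style brain model with
embedded white-matter fiber directions. The package then compares helmets at
the distribution level — do different helmets merely scale the brain strain
field, or reshape it? — and at the ranking level — does the choice of strain
metric change which helmet looks best?

## Coordinate convention and signal conditioning

All directional quantities use a headform-fixed Cartesian frame with origin
at the head centre of gravity: X posterior→anterior, Y right→left,
Z inferior→superior. The BrIC and UBrIC critical values are keyed to these
axis labels, so records must be expressed in this frame (the `coord_note`
attribute of every record restates it).

Laboratory channels are conditioned with a phaseless low-pass Butterworth
filter: one 2-pole pass forward and one backward (4 poles total), unit DC
gain, zero phase lag, and an amplitude ratio of 0.5 at the cutoff (the
square of a single −3 dB stage). The default cutoff is a literal 1000 Hz,
matching the printed specification of the laboratory conditioning; because
crash-test practice also speaks in SAE channel frequency classes,
`cfc_presets()` tabulates CFC 60/180/600/1000 with their −3 dB frequencies
(1.65 × class) for users who prefer that reading. Endpoints are handled by
odd-reflection padding of at least four filter time constants, and each
recursion pass is offset by its starting value so the zero-state transient
vanishes — a constant signal passes through bit-exactly.

Angular acceleration is never read from file: it is always derived from the
(by default, filtered) angular velocity by central differences, one-sided at
the record ends, with the ms→s conversion applied. Keeping a single
provenance for α(t) avoids silent inconsistencies between supplied and
derived channels. Whether to filter before differentiating is exposed as
`filter_first` (default `TRUE`); differentiating raw curves amplifies
high-frequency noise by ω, which is why the filtered route is the default.

## Kinematic metrics

* **PLA** and **PAV/PAA** are maxima of resultant magnitudes; PAA is
  reported in krad/s², the unit in which such summaries are conventionally
  tabulated.
* **HIC** uses a 15 ms window; the implementation scans every sample pair
  within the window using a cumulative trapezoid, and the test suite pins it
  to an exhaustive all-pairs search. An all-zero record yields 0, not an
  error.
* **BrIC** divides per-axis peak |ω| by (66.2, 59.1, 44.2) rad/s and takes
  the root-sum-square. Per-axis maxima are of absolute values and may occur
  at different instants — standard practice where the source is silent.
* **UBrIC** is implemented exactly as printed: the bracket
  `w* + (α* − w*) exp(−α*/w*)` summed over axes, then raised to `r = 2`.
  The cited original's r-norm variant (terms raised to `r`, then the 1/r
  root) is available behind `original_form = TRUE`. The degenerate case
  `w* = 0` with `α* > 0` is resolved by the analytic limit: the exponential
  kills the second term and the axis contributes 0.
* **DAMAGE** integrates the coupled 3-DOF system `M δ̈ + C δ̇ + K δ = −M α(t)`
  from rest with a fixed-step 4th-order Runge–Kutta scheme at the kinematics
  time step, and returns `β max‖δ‖` with β = 2.9903. The default M, K, C are
  transcribed from the published DAMAGE model (unit diagonal mass;
  kxx = 32142, kyy = 23493, kzz = 16935, kxz = 1636.3 N/m; C = 5.9148e-3 K);
  they are configuration inputs, and every correctness test uses synthetic
  single-axis configurations with closed-form step and steady-state
  responses, so the transcription is never load-bearing for the tests. The
  sign of the excitation does not affect max‖δ‖ for a zero-initial-state
  linear system driven by a sign-definite pattern, and the metric scales
  exactly linearly with input amplitude.

## Tract-related strain measures

Per element the Green–Lagrange tensor is `E = ½(FᵀF − I)`; its largest
eigenvalue (closed-form trigonometric solution, vectorised over elements and
time) is the principal strain. For white-matter elements the tensor is
expressed in an orthonormal frame whose first axis is the fiber direction:

* tract-oriented normal strain `ε_ton = E′₁₁` (signed, tension positive);
* tract-perpendicular normal strain `ε_tpn`: the larger eigenvalue of the
  2×2 perpendicular block;
* tract-oriented shear `ε_tos = √(E′₁₂² + E′₁₃²)`;
* tract-perpendicular shear `ε_tps`: half the difference of the
  perpendicular principal strains.

Three conventions deserve explicit statement because the verbal definitions
admit more than one reading:

1. **Deformed versus reference fiber.** The frame is built from the
   *real-time* (deformed) fiber direction `â(t) = F a₀/|F a₀|` by default,
   because the tract-deformation framework concerns the fiber as it moves
   with the tissue. The conventions genuinely differ — for
   `F = diag(1.2, 1, 1)` and `a₀ = (1,1,0)/√2` the along-tract strain is
   0.1298 (deformed) versus 0.11 (reference) — and `realtime_fiber = FALSE`
   switches to the reference convention for sensitivity checks.
2. **Shear convention.** Tensor (half-engineering) shear components are
   reported; `engineering_shear = TRUE` doubles the two shear outputs.
3. **Peak semantics.** Peaks are accumulated over time (running maximum).
   The along-tract normal peak is clamped at zero: axonal-injury reasoning
   concerns tensile stretch, and clamping keeps `MTON ≤ MPS` meaningful
   element-wise (the undeformed start of every history makes the clamp
   equivalent to including t = 0).

The perpendicular basis is completed deterministically (`e₂ ∝ â × c` with
`c` the canonical axis least aligned with `â`, `e₃ = â × e₂`); all four
measures are exactly invariant to this arbitrary choice and to rigid
rotations of the configuration, which the suite asserts to 1e-12.

Elements whose deformation gradient loses positivity (`det F ≤ 0` at any
time — numerical instability in an explicit solver) are flagged invalid,
excluded from all summaries and counted in the run log. Per-simulation
summaries use the interpolated percentile `k = 1 + q/100·(n − 1)` (R type 7)
at q = 95 — the percentile guards against exactly those few unstable
elements — over the whole brain for MPS and the white matter for the tract
metrics.

## Ensemble analyses

Curve similarity concatenates the three directional angular-velocity curves
(600 samples each) into one 1800-sample vector per record and correlates
helmet pairs at the same location: 136 pairs per location, 408 correlations
over three locations. Element-wise distribution similarity correlates paired
per-element strain peaks (whole brain for MPS, white matter for tract
metrics): 5 metrics × 3 locations × 136 pairs = 2040 correlations.
Coefficients are banded weak/moderate/strong at 0.3 and 0.7.

Location effects on the per-helmet summaries use two-sided Wilcoxon
matched-pairs signed-rank tests (pairs matched by helmet). Zero differences
are discarded — the standard signed-rank convention, so identical samples
report p = 1 — and the exact distribution is used for up to 25 non-zero
pairs, the normal approximation above. Significance is declared at p < 0.05.

Helmets are ranked per strain metric on the arithmetic mean of their three
location summaries, ascending (rank 1 = lowest strain), ties averaged.
Ranking agreement between metric pairs uses Kendall's tau-b: the
tie-corrected form is the right choice because averaged ties produce
non-integer ranks. Cross-metric Pearson correlations pool all 51
(helmet, location) observations — 35 kinematic×strain and 10 strain×strain
tests — flagging |r| > 0.7 as strong.

High-strain element sets take the `ceiling(fraction · n)` largest peaks
(default top 5%) with ties broken by element id, and normalised fields
divide element peaks by the same simulation's 95th-percentile summary, so by
construction roughly 5% of eligible elements exceed 1.

## The synthetic study

The generator's defaults *are* the study conditions: 17 helmets (A–Q) × 3
locations, one record per combination on the canonical grid. Per location
the dominant rotation axis (X for XRot, etc.) carries a damped main lobe
with a shallow rebound; off-axes carry 28% and 19% of the dominant peak, so
a typical helmet is dominant by at least 3×, consistent with a reported
typical XRot helmet (−24.4 / −6.9 / −4.7 rad/s). Dominant-axis peak
magnitudes are drawn per helmet from the observed per-location laboratory
statistics — XRot 27.6 ± 4.4, YRot 33.2 ± 3.8, ZRot 41.0 ± 2.1 rad/s,
clipped to the observed ranges — which also plants the ZRot > YRot > XRot
severity ordering the Wilcoxon analysis must recover. Helmet Q at XRot is
the outlier: comparable peaks on all three axes hitting
(11.7, 12.7, 9.6) rad/s within 1% (amplitudes are rescaled to the target
after jitter, so the realisation is exact), with delayed, oscillatory,
mixed-sign lobes whose timing was calibrated once so its concatenated-curve
correlation with any dominant-axis helmet stays below 0.35. Linear
acceleration pulses are scaled to peak resultants in a 75–180 g band with
per-location means near the laboratory values.

Strain fields live on an abstract raster-ordered element lattice
(default 5000 elements; coordinates exist only to make the spatial modes
smooth — no anatomical geometry is claimed). Region labels occupy contiguous
lattice blocks: 55% gray matter, 40% white matter (of which 5 points
corpus callosum and 5 points cerebellar white matter), 5% other. Each
element carries a fixed random symmetric unit direction tensor `D_e` and,
in white matter, a unit fiber vector drawn around a per-region mean
direction (dispersion 0.35). Per location, three shared smooth spatial
modes (low-frequency random cosine fields, weights 1/0.5/0.25) define the
common strain pattern; the outlier simulation draws an independent mode
set. The deformation is `F_e(t) = I + amp_e(t) D_e` with

```
amp_e(t) = g · sev · [ Σ_k w_k m_k(e) p_k(t) + σ η_e q(t) ]
```

where `sev = PAV/30` links strain severity to the record's angular-velocity
peak (so cross-metric correlations recover the strong angular-metric/strain
dependence), `g = 0.15` puts 95th-percentile MPS in the 0.2–0.35 range
typical of severe helmeted impacts, and the element noise level `σ = 0.35`
(relative to the spatial signal SD) was calibrated once so that
within-location element-wise peak correlations exceed 0.7 for every
non-outlier pair while the outlier's independent modes keep its pairs below
0.7. Because `D_e` is symmetric, the element eigenvalues of `F` are
`1 + amp·λ_i(D)`, and clipping `|amp|` at `0.6/‖D_e‖₂` guarantees
`det F > 0`; clipped elements are counted and logged. Everything is
reproducible: one master seed determines the ensemble bit for bit, and
sub-streams (kinematics, mesh, modes, per-simulation noise) are derived by
fixed small offsets.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no contact mechanics or helmet material response,
no biofidelic brain geometry or anatomically located strain concentrations,
symmetric deformation gradients (pure stretch; rotation invariance is
covered by dedicated analytic tests instead), and noise that is independent
across elements rather than spatially correlated measurement error.

## Numerical choices and degenerate inputs

* Canonical grid: 600 samples over 30 ms (samples at k·0.05 ms,
  k = 0..599), so three concatenated directional curves give exactly 1800
  correlation samples; resampling is linear and idempotent on conforming
  records.
* Filter: cutoff must lie below Nyquist (parameter error otherwise); DC
  unity is exact by the offset-correction construction.
* HIC of an all-zero record is 0; the optimiser window is reported
  alongside the value.
* DAMAGE: non-positive-definite mass is a parameter error; displacement
  norms exceeding 1e6 abort with a numerical error advising a smaller step.
* Tract strains on elements without a fiber vector are a contract error
  (they are only defined on white matter).
* Percentiles of an empty masked set are a data error, as is normalising by
  a non-positive summary (degenerate simulation).
* Wilcoxon with all-zero differences returns p = 1 rather than erroring.
* All error conditions carry classes (`helmstrain_format_error`,
  `_data_error`, `_parameter_error`, `_numerical_error`,
  `_contract_error`), and the pipeline wraps stage failures with the stage
  name and offending input id.

## Problem sizes used by the tests

The suite exercises ensemble-level properties at 250–2000 lattice elements
with 11–41 strain time steps; the structure-recovery and acceptance
analyses use the full 17 × 3 ensemble at 2000 elements, which the
vectorised tensor kernels process in seconds. These sizes were chosen as
the smallest at which the planted correlation structure is comfortably
resolved (the contracts also hold at the 5000-element default). Oracle
tests run brute-force comparisons — exhaustive HIC window search,
10⁴-direction sampling of the perpendicular strain plane,
characteristic-polynomial eigenvalues — at small n where exactness, not
speed, is the point.

## Known limitations

* The tract-strain constructions implement the verbal definitions of the
  four measures; the upstream framework's full derivation lives in its own
  appendix, and the discriminating deformed-versus-reference example above
  makes this package's committed reading testable rather than implicit.
* DAMAGE constants are transcribed configuration, not package science;
  users comparing against other implementations should confirm the
  constants match.
* The pipeline analyses element-indexed fields only; it does not voxelise,
  render anatomy, or compute volume-fraction measures (e.g. CSDM) or
  strain-rate metrics.
* Real laboratory ensembles carry correlated sensor noise, filter-phase
  artefacts and helmet-fit variability that the generator does not model;
  conclusions about real helmets require real curves, which the package
  reads through the same `read_kinematics()` interface.
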