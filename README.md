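# helmstrain

Computational injury-biomechanics pipeline for evaluating bicycle helmets
from laboratory oblique-impact tests. When a helmeted headform is dropped
onto an angled anvil, the recorded 6-DOF head kinematics (linear
acceleration a(t), angular velocity ω(t)) drive two complementary layers of
assessment:

1. **Kinematic injury metrics** computed directly from the loading curves:
   peak resultant linear acceleration (PLA), the Head Injury Criterion over
   a 15 ms window

   HIC = max over (t₁,t₂) of (t₂−t₁) · [ (1/(t₂−t₁)) ∫ a(t) dt ]^2.5,

   peak resultant angular acceleration and velocity (PAA, PAV), BrIC
   (root-sum-square of per-axis angular-velocity peaks over critical values
   66.2 / 59.1 / 44.2 rad/s), UBrIC

   UBrIC = { Σᵢ [ wᵢ* + (αᵢ* − wᵢ*) e^(−αᵢ*/wᵢ*) ] }^r,  r = 2,

   with per-axis peaks normalised by 211 / 171 / 115 rad/s and
   20.0 / 10.3 / 7.76 krad/s², and DAMAGE, β·maxₜ‖δ(t)‖ with β = 2.9903,
   where δ(t) solves the coupled 3-DOF oscillator M δ̈ + C δ̇ + K δ = −M α(t).

2. **Tissue-level strain metrics** post-processed from finite-element-style
   brain output. Per element, the Green–Lagrange tensor E = ½(FᵀF − I) is
   derived from the deformation-gradient history F(t). The largest
   eigenvalue gives the maximum principal strain (MPS). For white-matter
   elements carrying an axonal fiber direction a₀, E is rotated into a frame
   aligned with the deformed fiber â(t) = F a₀ / |F a₀|, yielding four
   tract-related measures: normal strain along the tract (MTON), peak normal
   strain perpendicular to it (MTPN), and shear strain oriented along (MTOS)
   and perpendicular to (MTPS) the tract. Peaks are accumulated over time
   and summarised per simulation by the 95th percentile (whole brain for
   MPS, white matter for the tract metrics).

On top of these, the package runs the ensemble analyses used to compare
helmets: Pearson correlations between concatenated directional
angular-velocity curves of helmet pairs (n = 1800 samples), element-wise
strain-distribution correlations within an impact location, top-5%
high-strain element sets and percentile-normalised fields, paired Wilcoxon
tests for impact-location effects, helmet ranking from location-averaged
strain summaries, Kendall's Tau agreement between rankings from different
metrics, and kinematic-versus-strain correlation tables.

Because laboratory curves and proprietary head-model output are not
redistributable, the package ships a seeded synthetic generator that
emulates the study design end to end: 17 helmets (A–Q) × 3 impact locations
(XRot/YRot/ZRot), each location rotating the head mainly about one anatomical
axis, one multi-axis outlier helmet (Q at XRot, per-axis peaks
11.7/12.7/9.6 rad/s), and spatially smooth element strain fields whose
within-location correlation structure is tunable.

## Worked example

```r
library(helmstrain)
library(dplyr)

cfg <- generator_config(seed = 1, mesh = list(
  n_elements = 2000, wm_fraction = 0.4, cc_fraction = 0.05,
  cerebellum_fraction = 0.05, other_fraction = 0.05
))
records <- generate_kinematics_ensemble(cfg)
rec <- records[["A_XRot"]]
rec
#> <kin_record> helmet A, XRot: 600 samples, dt = 0.05 ms, span 29.95 ms

cat("PLA:", round(pla(rec), 1), "g | HIC:", round(as.numeric(hic(rec)), 1),
    "| PAV:", round(pav(rec), 1), "rad/s | BrIC:", round(bric(rec), 3))
#> PLA: 120 g | HIC: 340.3 | PAV: 25.9 rad/s | BrIC: 0.408

setup <- strain_field_setup(cfg)
pk <- strain_peak_table(generate_strain_sim(rec, setup, cfg))
strain_summary(pk)
#> # A tibble: 5 × 4
#>   helmet_id location metric value
#> 1 A         XRot     MPS    0.198
#> 2 A         XRot     MTON   0.103
#> 3 A         XRot     MTPN   0.143
#> 4 A         XRot     MTOS   0.106
#> 5 A         XRot     MTPS   0.107

glance(curve_similarity_matrix(records, "XRot"))
#> # A tibble: 1 × 7
#>   n_helmets n_pairs  r_min r_max n_weak n_moderate n_strong
#> 1        17     136 0.0143 0.998     16          0      120
```

The XRot summary reads: helmet A's impact produces a 95th-percentile
whole-brain principal strain of about 0.20 and along-tract white-matter
strain of about 0.10; of the 136 helmet-pair curve correlations at XRot,
120 are strong (r > 0.7) and the 16 weak ones are exactly the pairs
involving the multi-axis outlier helmet Q.

`run_full(run_config(out_dir = "out", seed = 1))` executes the whole
pipeline (metric table, strain summaries, similarity heatmaps, location
tests, ranking, Kendall's Tau, metric correlations) and writes every result
as delimited text stamped with the package version, seed and config hash.

## Package tour

| area | functions |
| --- | --- |
| kinematics I/O | `read_kinematics()`, `write_kinematics()`, `resample_to_grid()`, `read_kinematics_ensemble()` |
| signal conditioning | `cfc_filter()`, `cfc_presets()`, `differentiate()`, `derive_angular_acceleration()` |
| kinematic metrics | `pla()`, `hic()`, `paa()`, `pav()`, `bric()`, `ubric()`, `damage()`, `metric_table()` |
| strain post-processing | `green_lagrange()`, `mps_history()`, `tract_strain_histories()`, `strain_peak_table()`, `strain_summary()`, `region_restrict()` |
| ensemble statistics | `curve_similarity_matrix()`, `strain_similarity_matrix()`, `top_fraction_elements()`, `normalize_field()`, `location_effect_test()` |
| ranking | `helmet_ranking()`, `kendall_tau_matrix()`, `metric_correlations()` |
| synthetic study | `generator_config()`, `generate_kinematics_ensemble()`, `generate_strain_ensemble()` |
| orchestration | `run_config()`, `run_full()` |

Result objects come with broom-style `tidy()`/`glance()` methods and
`autoplot()` heatmaps/bump charts. The methods vignette
(`vignettes/helmet-strain-analysis.Rmd`) documents the model assumptions,
parameter choices and known limitations.
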