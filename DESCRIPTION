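Package: helmstrain
Title: Tract-Related Brain Strain and Kinematic Injury Metrics for Helmeted Impact Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bicycle-helmet impact biomechanics. Reads,
    filters and differentiates 6-DOF headform kinematics; computes the seven
    kinematic head-injury metrics (PLA, HIC15, PAA, PAV, BrIC, UBrIC, DAMAGE);
    computes the maximum principal Green-Lagrange strain and four white-matter
    tract-related strain measures (normal and shear strain oriented along and
    perpendicular to the axonal fiber tract) from element deformation-gradient
    histories; summarises per-simulation 95th-percentile strain peaks; and runs
    the ensemble analyses: curve-similarity and element-wise strain-distribution
    Pearson correlations between helmets, paired Wilcoxon location-effect tests,
    helmet ranking with Kendall's Tau agreement across metrics, and
    kinematic-versus-strain metric correlations. A seeded synthetic generator
    emulates a 17-helmet by 3-location laboratory ensemble (including one
    multi-axis outlier helmet) plus finite-element-like strain fields so the
    whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    signal,
    deSolve,
    pracma,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
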