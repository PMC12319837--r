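Package: axisflux
Title: Day-to-Day Variability Along the Sensorimotor-Association Axis from
    Coherence Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dense-sampling functional connectomics in
    single individuals. Builds session-wise functional connectomes from
    parcellated BOLD time series using maximal-overlap discrete wavelet
    transform band-limiting and Welch magnitude-squared coherence, derives the
    sensorimotor-association (S-A) axis per session by diffusion map embedding
    with Procrustes alignment to a subject mean, and quantifies
    intra-individual variability along the axis: per-parcel standard
    deviations, Levene variance comparisons between subjects, decoding against
    external feature maps, parcel-wise covariate effect models with
    false-discovery-rate control, and within/between-network dispersion
    statistics with Bonferroni families.  Spatial inference uses
    hemisphere-aware spherical spin permutations.  A synthetic-data module
    generates parcellations, hormone-like covariate trajectories, planted
    axis loadings and coherent time series with known ground truth so that
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
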