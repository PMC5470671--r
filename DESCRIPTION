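Package: motornet
Title: EEG Motor-Network Coupling Biomarkers for Stroke Rehabilitation Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for deriving linear and cross-frequency (nonlinear)
    effective-connectivity biomarkers of upper-limb rehabilitation outcome
    from movement-task EEG. Simulates cue-locked oscillatory sources mixed
    through a lead field, preprocesses trial epochs to source-level
    baseline-corrected induced-power spectrograms (band-pass, artifact
    rejection, mid-sagittal flipping, pseudoinverse source projection,
    Morlet time-frequency transform), inverts a linear + cross-frequency
    coupling model of induced responses over five motor cortices by
    variational Laplace, compares model architectures with fixed- and
    random-effects Bayesian model selection, extracts band- and
    sign-resolved coupling features, and classifies favorable versus poor
    recovery with cross-validated logistic regression, band-combination
    search and backward elimination, plus clinical cohort statistics and
    subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
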