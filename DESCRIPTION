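Package: coactiv
Title: Meta-Analytic and Resting-State Functional Connectivity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-based meta-analysis and seed-based functional
    connectivity for neuroimaging. Implements activation likelihood
    estimation (ALE) over activation-focus databases, meta-analytic
    connectivity modelling (MACM) with seed-constrained experiment
    selection, permutation-based ALE difference maps with posterior
    probability thresholding and minuend masking, cluster-level
    family-wise-error correction by Monte-Carlo simulation, seed-based
    resting-state connectivity with a motion/tissue/principal-component
    nuisance model and band-pass filtering, minimum-statistic conjunction
    across modalities, and binomial base-rate functional characterization
    against a behavioural label taxonomy. Includes generators for
    synthetic foci databases with planted co-activation networks and for
    synthetic BOLD data with planted seed-target correlations and
    realistic confounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
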