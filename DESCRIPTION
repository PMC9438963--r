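Package: cpmpred
Title: Connectome-Based Predictive Modelling of Behavioural Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modelling (CPM) of continuous
    behavioural change scores from resting-state functional connectivity.
    Implements covariate-controlled partial Spearman edge selection over the
    upper-triangle edge space of a parcellated connectome (AAL-116 by
    default), positive/negative network-strength scores, leave-one-out
    cross-validated linear prediction, selection-threshold grid search,
    permutation significance testing with Benjamini-Hochberg false discovery
    rate correction, consensus-edge anatomy reports, and framewise
    displacement based motion quality control. Ships a synthetic-cohort
    generator with planted signal edges and known ground truth so every
    stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
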