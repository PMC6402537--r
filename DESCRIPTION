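Package: pfcdose
Title: Dose-Effect Analysis of Prefrontal Ensemble Recordings in a
    Covert-Attention Task
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the neurophysiological and behavioral
    analysis of multielectrode prefrontal recordings collected under a
    placebo-flanked oral dosing schedule (e.g. methylphenidate vs placebo)
    during a four-location covert-attention task.  Provides a synthetic
    session generator with shared-latent correlated variability, a
    plain-text session format, spike-density and epoch-count preprocessing,
    Kruskal-Wallis selectivity classification, the 19 single-neuron
    response metrics and their per-dose ANOVA scan with Bonferroni
    bookkeeping, pairwise noise/signal correlations with sign-split
    summaries and correlation-structure curves, cross-validated linear
    maximum-margin ensemble decoding with label-permutation nulls, and
    session-level behavioral statistics, orchestrated by a deterministic
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
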