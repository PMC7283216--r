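Package: pgpde
Title: Personalised Gaussian-Process Differential Expression and Pathway
    Enrichment for Matched Case-Control Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed features between matched
    case-control pairs in irregularly sampled time-course omics data by
    Gaussian-process model selection.  Each feature in each pair is scored by a
    Bayes factor comparing separate case/control GP fits against a joint fit,
    with marginal likelihoods integrated over hyperparameters by a central
    composite design; fixed pre-event time windows are scored by the symmetric
    Kullback-Leibler divergence between the models' predictive distributions.
    Per-pair gene lists are combined at pathway level with a permutation test
    on an adjusted geometric mean of scaled pathway overlaps, with
    Benjamini-Hochberg correction.  A population-wide baseline (pooled
    case/control scoring plus one-sided Fisher's exact test) and a synthetic
    matched-pair data generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
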