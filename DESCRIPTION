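Package: cmpunit
Title: Single-Unit Analysis of the Constructive Memory-Perception Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reimplements, as a tested and reusable pipeline, the complete
    single-unit spike-train analysis of the constructive memory-perception
    (CMP) task: the task's rotation geometry mapping an item's remembered
    co-location and a rotated background orientation onto a saccade target;
    sliding-window one-way and nested three-way ANOVA neuron-classification
    screens; the Fisher-Z-averaged co-location index with its permutation
    test; permutation-calibrated ROC discriminability; orientation-tuning
    similarity across co-locations; the matching index over rotation
    patterns; target-signal population time courses; and the error-trial
    partial-correlation analysis.  An inhomogeneous-Poisson synthetic
    session generator with ground-truth neuron archetypes (unitized item
    coding, background tuning, convergence, transference, targeting) makes
    every stage verifiable without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
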