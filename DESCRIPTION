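Package: grsig
Title: Joint Transcriptional-Signature and Growth-Rate Analysis of Drug
    Response Screens
Version: 0.1.0
Authors@R:
    person("LJP", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint molecular and phenotypic analysis of
    perturbational drug screens profiled with the L1000 landmark-gene
    assay and viable-cell counting. Computes characteristic-direction
    differential-expression signatures against same-plate vehicle
    controls, scores replicate consistency against a batch-specific
    empirical null (Signature Consistency Score), clusters consistent
    signatures by fuzzy c-means on cosine geometry with consensus over
    repeated runs, builds percentile-thresholded signature networks,
    converts cell counts to normalized growth-rate inhibition (GR)
    metrics, cross-tabulates molecular and phenotypic responses into
    four response classes, and scores drug-combination synergy as
    excess over Bliss independence on the GR scale. Includes a
    synthetic-data generator that emulates the plate/replicate/dose
    design of such screens with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
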