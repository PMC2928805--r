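Package: nemaphene
Title: Quantitative Phenotyping of C. elegans Neuromuscular Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for classic C. elegans neuromuscular
    assays: body-posture head-bend analysis from a 13-point midline (the
    "first supplementary angle"), centroid tracking and average locomotory
    speed from time-lapse image stacks, fluorescence puncta quantification by
    background-subtracted linescan peaks, and evoked postsynaptic current
    metrics (peak amplitude, half-time decay, charge integral, peak-normalized
    traces). Includes seeded synthetic-data generators for each modality with
    analytic ground-truth sidecars, and the group statistics used with such
    assays (mean +/- s.e.m., Welch t-test, one-way ANOVA, Dunnett's multiple
    comparison with Monte-Carlo adjusted p-values).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
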