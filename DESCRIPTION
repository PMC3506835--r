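Package: xconcord
Title: Cross-System Concordance Analysis of Transcriptomic Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparing transcriptomic responses measured in
    two experimental systems, built around a three-condition in vivo insult
    experiment (sham / insult / insult plus drug) and a paired in vitro
    stimulation experiment. Implements detection-call filtering of
    probeset-level microarray intensities, probeset-to-gene averaging on the
    linear scale followed by log2 transformation, per-gene differential
    expression (Welch t, paired t, one-way ANOVA) with Storey q-values,
    rank-based Gene Ontology association with signed log10 scores,
    cross-system concordance analysis (correlation, quadrant contingency,
    Fisher association, prediction sensitivity and specificity, GO-restricted
    refinement), drug-attenuation analysis, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
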