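Package: notchscore
Title: Knowledge-Based Bayesian Network Scoring of Notch Pathway Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers a per-sample log2-odds score of functional Notch signal
    transduction pathway activity from the expression of 18 curated direct
    NOTCH target genes, using a three-layer Bayesian network (latent
    transcription-complex state, latent per-gene transcription states,
    observed discretized probeset intensities). Provides calibration on
    labeled two-class cohorts, model freezing and serialization, exact
    posterior inference with a brute-force enumeration oracle, expression
    matrix input/output with quantile normalization and sample quality
    control, a synthetic cohort generator for calibration contrasts and a
    T-cell acute lymphoblastic leukemia style clinical cohort, and the
    downstream clinical pipeline: NOTCH1/FBXW7 mutation-strength
    classification, Kruskal-Wallis group comparison, ICN1 correlation,
    percentile activity grouping, Kaplan-Meier/log-rank survival analysis
    and PTEN contingency association.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    limma,
    stats,
    survival,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
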