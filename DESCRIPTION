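Package: methagg
Title: Bias-Aware Comparison of Sparse Methylation Signals Across Functional Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing per-CpG DNA methylation signals across
    functional boundaries (intron-exon, UTR-coding, CpG-island edges) in the
    presence of structured missing data. Aggregation matrices of per-site
    methylation rates are summarised by column, row and matrix averages,
    whose divergence under deamination-driven CpG depletion produces
    Yule-Simpson artifacts in naive metaplot comparisons. The package
    provides a randomization diagnostic that detects such artifacts, a
    non-parametric Paired Region Averaging correction with rank-based
    testing, and COMPARE, a per-column logistic-regression matrix-completion
    model that infers site-specific methylation tendencies with built-in
    cross-validation scored by a total-least-squares line. Simulators with
    known ground truth, including a deamination-coupled generator, support
    calibration and end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
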