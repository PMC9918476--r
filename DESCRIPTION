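Package: sigaudit
Title: Tumor-Intrinsic Specificity Auditing of Transcriptomic Subtype Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate whether bulk-tumor transcriptomic subtype
    signatures reflect neoplastic cells or contaminating tissue compartments.
    Provides gene-set scoring (mean log2 expression, with mean-centered/scaled
    variants), from-scratch resampled k-means consensus clustering for sample
    subtyping and gene-based signature decomposition, self-contained Spearman
    and Wilcoxon rank-sum statistics, purity-correlation and paired
    primary/model-system retention analyses, rule-based tumor-intrinsic
    verdicts, a generic top-scoring-pairs single-sample classifier, and a
    synthetic bulk-expression cohort generator with full ground truth
    (purity-weighted compartment mixtures over tumor, acinar, immune and
    fibroblast profiles) so that every stage is testable without external
    datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
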