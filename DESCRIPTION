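Package: glycoprofiler
Title: Serum Glycopattern Profiling and Lectin-Enriched Glycoproteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for serum glycoproteomics biomarker
    studies built around lectin microarrays and lectin-affinity enriched
    LC-MS/MS. Implements background-based spot filtering and per-block
    median-sum normalization of lectin microarray intensities, replicate
    aggregation and paired differential glycopattern analysis with
    hierarchical clustering; run-depth normalization of spectral counts
    and spectral-index label-free quantification with fold-change
    regulation calls and identification-set accounting; glycoprotein
    category classification with a built-in N-X-S/T sequon scanner;
    iterative position-specific binomial motif enrichment over fixed-width
    glycosite windows; and lectin/glyco-antibody microarray validation
    with ROC/AUC biomarker evaluation. A synthetic-data module generates
    every input format with known ground truth so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
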