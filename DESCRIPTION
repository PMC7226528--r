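Package: cyclinpair
Title: Paired Tumor-Normal D-Type Cyclin Deregulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for paired tumor/normal expression cohorts
    centred on the D-type cyclins (CCND1, CCND2, CCND3) in head and neck
    squamous cell carcinoma. Computes per-patient tumor-vs-normal fold
    changes and classifies each patient as upregulated, unchanged or
    downregulated against fixed fold-change thresholds; cross-tabulates
    calls between cyclins to quantify compensatory (opposite-direction)
    coupling with a permutation test; derives an expression-based surrogate
    for 11q13 locus co-amplification from fold-change profiles of genes in
    a fixed window around an anchor gene; and stratifies Kaplan-Meier,
    log-rank and univariate Cox survival analyses by deregulation group.
    Includes microarray-style preprocessing (quantile normalization,
    technical-replicate averaging, probe-to-gene collapsing, intensity
    filtering) and a median-of-ratios count path, plus a synthetic paired
    cohort generator with ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    rtracklayer,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
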