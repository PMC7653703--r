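Package: cnvprog
Title: Copy-Number Instability and Recurrence Prognosis in Pituitary
    Neuroendocrine Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of array-CGH copy-number profiles for
    pituitary neuroendocrine tumor (PitNET) prognosis: derivative log
    ratio spread quality control, profile normalization and
    centralization, circular binary segmentation with permutation-based
    change-point acceptance, copy-neutral LOH calling from SNP-probe
    homozygosity runs, genomic instability burden metrics, unsupervised
    clustering of alteration profiles (Jaccard distance, Ward
    criterion), burden-recurrence logistic models with likelihood-ratio
    tests, genome-wide per-probe and per-gene association scans under
    Benjamini-Yekutieli and Benjamini-Hochberg control, and integration
    with tumor transcriptomes via differential expression and preranked
    gene set enrichment analysis. Includes a synthetic cohort generator
    emulating the statistical structure of a multi-type PitNET aCGH
    study so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
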