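Package: pairedmet
Title: Paired Primary/Metastasis Exome Analysis: Somatic Filtering, CNV
    Tracks, LOH Mixture Modelling and Gene-Family Enrichment
Version: 0.1.0
Authors@R:
    person("Paired", "Met Developers", email = "pairedmet@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for paired tumor/germline exome
    data from primary tumors and their metastases. Implements somatic
    variant filtering with explicit threshold rules and QC flags,
    per-SNP log2 coverage-ratio copy-number tracks with moving-average
    smoothing and segment calls, a Beta-Normal mixture model on major
    allele frequencies estimating loss-of-heterozygosity fraction,
    tumor content and whole-genome-amplification allelic dropout, an
    exact binomial SNP-phase concordance test between paired lesions,
    gene-family (AKAP) mutation enrichment summaries with Fisher's
    exact test, and a seeded simulator of paired exome datasets used as
    ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
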