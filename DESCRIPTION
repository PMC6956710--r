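Package: fibrointegra
Title: Integrated DNA Methylation and Transcriptome Analysis of Uterine
    Fibroid Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Methylation-based subtype discovery and integration tools for
    uterine fibroid cohorts profiled on Infinium-style beta-value arrays with
    matched RNA-seq counts and chromosome-X allelic read counts. Implements
    variable-probe selection, hierarchical and consensus clustering with
    sample- and cluster-level stability scores, rule-based subtype
    classification (MED12 mutation, HMGA1/HMGA2 overexpression),
    per-probe differential methylation with beta-difference and
    significance thresholds, distal transcription-factor binding-site
    hypergeometric enrichment, promoter-methylation/expression starburst
    integration, directional differentially-expressed-gene overlap tests,
    X-inactivation-based clonality inference for tumour pairs, and A/B
    chromatin-compartment reconstruction from binned methylation
    correlation eigenvectors. A synthetic cohort generator with a recorded
    truth bundle supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR
Config/testthat/edition: 3
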