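Package: netsnp
Title: Candidate-Gene Network Expansion and SNP Survival Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Expands candidate genes to network-context focal genes using local
    pathway (GMT) and protein-protein interaction (SIF/TSV) snapshots, filters
    SNP annotations to central SNPs located in coding or regulatory regions,
    links central SNPs to tag-SNPs through pairwise linkage disequilibrium
    computed from unphased genotypes with a two-locus haplotype EM, reconciles
    deleteriousness predictions from four protein-effect predictors, and
    screens SNPs for survival association with Kaplan-Meier estimation,
    log-rank tests and logistic-regression odds ratios. Includes a synthetic
    data generator that emulates every input format with controllable
    linkage-disequilibrium and survival-effect structure, so the full pipeline
    runs and is testable without any database access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
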