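Package: herdcnv
Title: Cross-Panel Concordance and Haplotype-Based Imputation of Copy
    Number Variants Called from SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pedigreed livestock populations genotyped on a
    high-density SNP array with a nested medium-density subset, renders
    Log R Ratio and B allele frequency signals with planted copy number
    variants (CNVs), calls CNVs with a five-state hidden Markov model
    (Viterbi segmentation with GC-wave adjustment, a minimum-SNP rule and
    an optional per-segment Bayes factor), classifies the overlap of
    calls between the two panel densities, and evaluates haplotype-based
    imputation of CNV copy number from flanking SNPs: consensus calling
    across two callers, frequency-based locus selection, midpoint
    tri-allelic or split bi-allelic marker encoding, an oldest-80
    percent reference split, a haplotype-copying imputer, and the full
    evaluation suite (per-state accuracy, adjusted Rand index, ANOVA
    with Tukey contrasts, Pearson correlations with Fisher r-to-z
    intervals, and Bayes-factor comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    vcfR
Config/testthat/edition: 3
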