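Package: snpload
Title: Cross-Population Allele-Frequency Tests and Expected Allele Load
    for Candidate Behaviour SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare a candidate-SNP panel across populations:
    reconstruction of allele counts from published allele frequencies,
    pairwise two-sided Fisher exact tests with odds ratios and Woolf
    confidence intervals, five multiple-testing corrections (Bonferroni,
    Holm, Sidak, Benjamini-Hochberg, Storey q-values), and the
    Hardy-Weinberg expected allele-load statistic (2p summed over loci)
    with t and Wilcoxon cross-population comparisons. Includes a
    synthetic-cohort simulator (HWE genotypes with optional inbreeding,
    minimal VCF output) so the full pipeline is testable without external
    genotype downloads. Ships a transcription of a published 24-variant
    behaviour-associated SNP panel with allele frequencies for six
    1000 Genomes populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
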