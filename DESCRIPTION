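Package: poolqtl
Title: Pooled Whole-Genome-Resequencing QTL Scans for Ascites Syndrome in
    Broiler Chickens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Case/control QTL scanning from pooled whole-genome resequencing
    (pool-seq) allele counts, built around the Res-Sus SNP-frequency-difference
    statistic: per-pool allele frequency estimation, replicate averaging by
    phenotype and sex, deterministic cluster-based candidate-region calling
    with sex-specificity and direction classification, and per-chromosome SNP
    density summaries. Validation statistics for candidate loci include
    genotype-phenotype association tests with expectations drawn from
    whole-population genotype frequencies (Excel-semantics chi-square with
    simple Bonferroni adjustment), Hardy-Weinberg equilibrium checks,
    two-locus combined-genotype epistasis screens, odds summaries, and
    delta-delta-Ct relative-expression analysis. A liability-threshold
    synthetic pool-seq generator with truth tables makes every stage testable
    without the original sequencing pools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
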