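# poolqtl

QTL mapping for ascites syndrome (pulmonary hypertension syndrome) in
broiler chickens from pooled whole-genome resequencing, plus the
genotype-level statistics used to validate candidate loci. The package is
aimed at poultry and livestock geneticists running case/control pool-seq
scans: phenotyped birds are pooled by phenotype and sex, each pool is
sequenced, and per-SNP read fractions stand in for population allele
frequencies.

## The statistic at the core

For SNP *i*, pool *j*, the pool frequency is `f_ij = alt_ij / depth_ij`.
Biological replicates are averaged unweighted within each phenotype x sex
group, and the scan statistic per sex *s* is the **Res−Sus SNP frequency
difference**

```
d_is = mean_reps f(resistant, s) − mean_reps f(susceptible, s)
```

with `d > 0` meaning the non-reference allele tracks resistance. Candidate
QTL regions are clusters of consecutive SNPs with `|d| ≥ 0.20` and a
common sign (at most 20 kb between members, at least 10 members; nearby
clusters from either sex merge within 50 kb). Regions are classified by
sex pattern (both / male-only / female-only, threshold inclusive at 20%)
and direction (resistance vs susceptibility per sex).

Candidate loci are validated on individually genotyped birds: expected
phenotype counts per genotype class come from the whole population's
genotype frequencies, each class gets a two-cell chi-square (df = 1,
spreadsheet CHITEST semantics) with a simple Bonferroni adjustment over
the tested classes (class frequency must exceed 10%), Hardy–Weinberg
agreement is checked from allele frequencies, two-locus epistasis is
screened over the 9 combined genotype classes, and expression differences
use the ΔΔCt method (`fold = 2^−ΔΔCt` against a TBP reference) with
one-tailed Welch t-tests.

A liability-threshold simulator (`simulate_poolseq()`) generates cohorts,
pools and reads with truth tables so the whole pipeline is testable
without sequencing data.

## Worked example

Classify the 28 published candidate regions (shipped as a fixture) and
reproduce the summary splits:

```r
library(poolqtl)
regions <- classify_regions(load_fixture("table1_regions"))
summarize_regions(regions)
#> 28 candidate region(s) on 13 chromosome(s)
#>   sex pattern: both=15, male_only=8, female_only=5
#>   direction:   res_both=8, sus_both=1, res_male_only=5, sus_male_only=3,
#>                res_female_only=3, sus_female_only=2,
#>                res_male_sus_female=2, sus_male_res_female=4
```

15 regions are associated in both sexes, 8 only in males, 5 only in
females; most show the non-reference alleles tracking resistance.

Single-locus association on the reconstructed LRRTM4 genotype counts:

```r
a <- associate_counts(load_fixture("table2_lrrtm4"))
a[a$significant, c("subset", "class", "n", "p_adj")]
#>   subset class   n       p_adj
#> 1    all    AG 246 0.004949659
#> 4 female    AG 113 0.044906312
```

The homozygous non-reference class (AG) is significantly enriched for
susceptible birds in females and overall; no male single-locus class is
significant. The two-locus screen flags the male LRRTM4-het x
CPQ-hom-nonref class (RRCC, adjusted P = 0.017), whose odds of resistance
are:

```r
t3 <- load_fixture("table3_combined")
rrcc <- t3[t3$subset == "male" & t3$genotype == "RRCC", ]
odds_of_resistance(rrcc$obs_res, rrcc$obs_sus)
#> $odds
#> [1] 5.777778
#> $label
#> [1] "6:1"
```

An end-to-end synthetic run lives in `analysis/01_simulate.R` through
`analysis/06_expression.R`; each script prints what it found and writes
its tables under `results/`.

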