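---
title: "Pool-seq QTL scanning and validation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq QTL scanning and validation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolqtl)
```

## The experimental design this package models

A hatch of phenotyped broilers (susceptible or resistant to ascites after
a hypobaric challenge) is split by phenotype and sex; duplicate pools of
equal DNA amounts from 10 birds each give 8 pools, each sequenced to a
mean depth around 66x. Per SNP and pool, the fraction of reads carrying
the non-reference allele estimates that pool's allele frequency. The scan
statistic is the per-sex difference of replicate-averaged frequencies,
resistant minus susceptible (`diff_track()`); a positive value means the
non-reference allele is more common in resistant birds.

Two error sources sit under every estimate: pool composition (10 birds
per pool, so bird-sampling variance f(1−f)/20 per pool) and read sampling
(binomial with the realized depth). Replicate averaging halves both. The
caller therefore never tests single SNPs; it requires runs of many
consecutive SNPs sharing a large differential, which in real data arise
from haplotype blocks in linkage with a causal variant.

## Region calling

The published scan was visual (tracks inspected in a genome viewer). We
formalize it deterministically in `call_regions()`:

* membership: `|d| >= threshold` (default 0.20, inclusive so that a
  printed "20%" qualifies) with a common sign within a run;
* contiguity: consecutive members at most `max_gap_bp` (20 kb) apart;
* support: at least `min_snps` (10) members;
* merging: called intervals from either sex within `merge_bp` (50 kb) on
  one chromosome merge, keeping per-sex supporting counts and signed peak
  differentials; a sex with no supporting cluster reports 0, the
  convention of the published region table.

The defaults were chosen so that regions at the published scale
(0.02–0.40 Mbp, with the strongest block spanning ~700 SNPs over 55 kb)
are callable while an 8-pool null track (where `sd(d) ≈ 0.13` at 66x)
essentially never produces a 10-SNP same-sign run above 0.20: the per-SNP
exceedance probability is ~0.12, and its 10th power is negligible over a
few thousand independent sites. All four knobs are exposed as arguments.

Classification (`classify_region()`) is threshold-inclusive and
sign-driven; a region associated in neither sex is rejected rather than
silently classified, since such a row cannot occur in a called set.

## Association statistics

`associate()`/`associate_counts()` reproduce the validation procedure
exactly as practiced rather than a textbook contingency test:

* expected counts per genotype class come from the subset's overall
  phenotype rate (`exp_sus = n_class * total_sus / total`);
* each class is tested with a two-cell goodness-of-fit chi-square at
  df = 1 — the spreadsheet CHITEST convention for a 1-row range — not a
  3x2 table test;
* classes whose subset frequency does not exceed 10% are reported
  untested and excluded from the Bonferroni multiplier, which is the
  count of tested classes in the same subset (up to 3 single-locus, up to
  9 two-locus);
* adjusted P-values are capped at 1 (the uncapped spreadsheet values are
  carried in the fixtures for reference);
* individuals of unknown sex contribute to the "all" subset only.

Because expectations are estimated from the same margin as the
observations, the per-class test is conservative for large classes (the
variance of `obs − exp` is deflated by `1 − n_class/n`); this is a
property of the procedure being modeled, and our type-I simulations show
family-wise error comfortably below the nominal 5%.

Published tables print percentages, not counts, so fixture counts are
reconstructed as `round(n * pct / 100)` with halves away from zero (the
spreadsheet convention); this perturbs reconstructed P-values by up to
roughly 15% relative, which is the tolerance the fixture-based checks
use. One printed cell (the female GA/CC pair, which sums to 133%) is
repaired as the complement of its cleanly printed partner; the fixture
header documents this.

## The synthetic-data generator

There is no generative model in the source study (it is an observational
line study), so the generator is this package's own design, chosen to
produce data with the statistical structure the scan assumes:

* **Liability threshold.** Genotypes are Binomial(2, f) founders (HWE,
  sites independent); liability is the sum of sex-specific per-copy
  effects, optional pairwise dosage-product (epistasis) terms, and
  Gaussian noise (sd 1). The susceptible fraction is fixed exactly at
  `prevalence_target` by the empirical liability quantile, so truth
  tables are exact per run. The chamber-trial prevalence is not published;
  the default 0.5 maximizes information per bird and is a free choice.
* **QTL blocks.** A QTL spans `n_snps` perfectly linked SNPs over
  `span_bp`. This is complete LD, not LD decay — enough to give the
  caller the clustered signal real haplotypes provide, without modeling
  recombination. Effect sizes are expressed on the liability scale; the
  truth table reports the realized frequency differentials (the scan's
  units, 20–60% in the published regions), computed over the pooled birds
  so the read-sampling error bound `3·sqrt(f(1−f)(1/D_res + 1/D_sus))`
  applies directly.
* **Pools and reads.** Disjoint random draws of 10 birds per cell and
  replicate, equal contribution per bird; depth Poisson(66); alt counts
  Binomial(depth, f*) with a symmetric error fold-in
  `f* = f(1−e) + (1−f)e`, default e = 0.002. No mapping bias, no unequal
  DNA contribution, no index hopping.
* **Neutral background.** SNP density scales linearly with chromosome GC
  (the microchromosome pattern), frequencies Uniform(0.05, 0.95); the
  default layout is three desk-scale chromosomes (2, 1.5, 1 Mbp at 42,
  48, 56% GC).

What passing tests do show: the scan recovers implanted differentials
within read-sampling error, calls regions over implanted blocks, and
stays silent on nulls. What they do not show: behaviour under LD decay,
mapping artifacts, pool-construction error, or reference bias — real-data
phenomena outside the generator.

## Numerical and interface choices

* Coordinates are 1-based inclusive internally (positions are quoted in
  bp); BED/bedGraph output converts to 0-based half-open, .seg stays
  1-based.
* Only biallelic SNPs are accepted; multi-allelic VCF records are dropped
  with a warning count. Missing per-sample allelic depths become depth 0
  at that site, masking rather than dropping the site.
* Replicate pools below `min_depth` (default 10) at a site are excluded
  from that site's group mean — a proxy for the unspecified
  "high-quality SNP" filtering upstream; a group with no passing
  replicate is NaN and propagates.
* Zero-depth frequencies are NaN, never errors; `alt > depth` is always
  an error.
* The Welch comparison is one-tailed by default ("one way, unequal
  variance"): P is half the two-tailed P of |t|, so identical groups give
  exactly 0.5. Degenerate zero-variance pairs are errors, not P-values.
* Ct records above the 25-cycle budget are "not detected" and excluded
  before technical-replicate averaging; ΔΔCt here is ΔCt against the
  reference gene (no calibrator sample), matching how the assay reports
  relative expression.

## Problem sizes in the test suite

The packaged tests run the generator at desk scale: cohorts of 160–600
birds, 300–5000 neutral SNPs, QTL blocks of 40 linked SNPs with
liability effects of 2 sd (realized |d| around 0.4–0.6). These sizes were
chosen as the smallest at which the properties under test (recovery
within 3 SE, caller sensitivity and null specificity, association power
at a +25-point class effect under the 8/10-run guarantee for effects of
15 points or more, per a pre-hoc power calculation at n = 600) hold with
comfortable Monte-Carlo margins. The analysis scripts under `analysis/`
run a 600-bird, ~5100-SNP cohort matching the study design end to end.

## Known limitations

* The cluster caller's defaults formalize a visual procedure; different
  `min_snps`/gap settings change region boundaries, and the merge step
  can join adjacent causal blocks (the analysis run shows one epistatic
  block merged into its partner's region when their differentials sit at
  the threshold).
* Reconstructed fixture counts are ±1 of the archived ones; adjusted
  P-values inherit that uncertainty, and one published adjusted P (the
  whole-cohort hom-nonref class) is not reproduced by any straightforward
  reading of the stated procedure — our computation gives ~0.005 against
  a printed 0.0083. Significance calls agree throughout.
* The generator draws founders independently per site; allele-frequency
  spectra, LD decay and selection history of a real closed line are not
  emulated.
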