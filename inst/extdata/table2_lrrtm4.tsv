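# Single-locus genotype-by-phenotype summary for the LRRTM4 region qPCR assay
# in REL line birds, one row per subset x composite genotype. Genotype codes:
# GA = homozygous reference, RR = heterozygous, AG = homozygous non-reference.
# pct_sus/pct_res are the published phenotype percentages within the class;
# p_adj_printed is the published Bonferroni-adjusted P (Excel-style, uncapped).
# Counts are reconstructed downstream as round(n * pct / 100) and may differ
# from the archived counts by +/-1.
subset	genotype	n	pct_sus	pct_res	p_adj_printed
all	AG	246	45.6	54.4	0.0083
all	RR	426	31.0	69.0	0.13
all	GA	197	34.5	65.5	1.76
male	AG	101	41.6	58.4	0.24
male	RR	192	27.7	72.3	0.21
male	GA	86	36.5	63.5	1.65
female	AG	113	47.8	52.2	0.047
female	RR	157	32.7	67.3	0.83
female	GA	81	29.6	70.4	0.52
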