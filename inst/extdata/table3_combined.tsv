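# Two-locus (LRRTM4 x CPQ) combined-genotype phenotype summary in REL line
# birds, one row per subset x composite class. LRRTM4 codes GA/RR/AG and CPQ
# codes TA/YM/CC order hom-ref/het/hom-nonref; e.g. RRCC = LRRTM4 heterozygote
# with CPQ non-reference homozygote. p_adj_printed as published (uncapped).
# The female GA/CC pct_sus is reconstructed as 100 - pct_res (the published
# cell is a typographic error: the printed pair sums to 133).
subset	lrrtm4	cpq	n	pct_sus	pct_res	p_adj_printed
all	AG	TA	23	56.5	43.5	0.375
all	AG	YM	26	50.0	50.0	6.107
all	AG	CC	72	36.4	63.6	6.910
all	RR	TA	33	33.3	66.7	1.488
all	RR	YM	31	42.9	57.1	4.935
all	RR	CC	131	25.8	74.2	0.080
all	GA	TA	15	38.8	61.2	4.198
all	GA	YM	14	25.8	74.2	0.620
all	GA	CC	54	40.0	60.0	6.187
male	AG	TA	11	45.5	54.5	3.067
male	AG	YM	12	44.4	55.6	5.380
male	AG	CC	36	50.0	50.0	7.575
male	RR	TA	18	25.0	75.0	2.340
male	RR	YM	15	46.7	53.3	2.026
male	RR	CC	61	14.8	85.2	0.033
male	GA	TA	8	30.6	69.4	2.488
male	GA	YM	8	14.8	85.2	0.582
male	GA	CC	19	44.4	55.6	2.382
female	AG	TA	11	63.6	36.4	1.081
female	AG	YM	12	57.1	42.9	8.443
female	AG	CC	31	0.0	100.0	3.449
female	RR	TA	7	41.7	58.3	3.371
female	RR	YM	12	27.3	72.7	3.259
female	RR	CC	53	36.5	63.5	4.818
female	GA	TA	2	48.4	51.6	2.139
female	GA	YM	5	36.5	63.5	3.403
female	GA	CC	22	30.8	69.2	2.661
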