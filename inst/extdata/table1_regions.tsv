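# Candidate QTL regions for ascites syndrome from pooled WGR of the REL line.
# One row per called region: chromosome, interval in Mbp (GRCg6a), size in Mbp,
# peak Res-Sus SNP frequency difference (percent, signed) per sex, and the
# published free-text gene list (stored verbatim, including typeset oddities).
# Positive differences mean the non-reference allele is more frequent in
# resistant birds.
chrom	start_mbp	stop_mbp	size_mbp	male_diff_pct	female_diff_pct	genes
1	48.18	48.41	0.23	30	30	APLD,GPRC5A,HEBP1,FAM234B,GSG1,EMP1,MIR6581
1	170.48	170.53	0.05	40	0	CAB39L
1	175.68	175.87	0.19	-25	30	PDS5B
1	182.31	182.46	0.15	40	20	AASDHPPT,KBTBD3,MSANTD4
1	183.65	183.95	0.30	35	35	DCUN1D5,MMP13,MMP10,MMP3,MMP7,BIRC2
2	22.86	23.03	0.17	50	0	SAMD9L,HEPACAM2,VP50
2	34.47	34.61	0.14	40	-20	PLCL2
2	91.85	91.92	0.07	50	0	CNDP2,FAM69C
2	95.14	95.22	0.08	-30	0	CDH19
2	122.75	122.83	0.08	45	-25	CA2
2	126.97	127.09	0.12	40	20	CPQ
3	37.27	37.36	0.09	-30	40	RYR2
3	48.98	49.00	0.02	-20	30	RMND1
3	50.41	50.44	0.03	40	0	SCAF8
3	100.70	101.10	0.40	0	-30	OSR1
4	36.72	36.90	0.18	40	0	GRID2
5	13.26	13.29	0.03	0	50	DDTNFR23, CARS
5	25.44	25.47	0.04	-50	25	SPTBN5
6	28.82	28.87	0.05	0	40	ABLIM1
10	6.49	6.54	0.05	40	30	TJP1
14	1.48	1.66	0.18	0	30	LMTK2,BHLHA15,TECPR1,BRI3,BAIAP2L1,NPTX2
20	9.06	9.10	0.04	0	-40	PXDNL,PCMTD2
22	4.40	4.48	0.08	60	20	LRRTM4
27	7.85	7.98	0.13	-30	0	RAMP2,WNK4,COA3,BECN1,PSME3,AOC3,G6PC,PTGES3L,RPL27,IFI35,VAT1,RND2
28	0.59	0.63	0.05	-25	0	TIMM44,HNRNPM
Z	18.60	18.73	0.13	-25	-50	PDE4D
Z	19.10	19.50	0.40	25	50	ZSWIM6,KIF2A
Z	33.87	33.90	0.03	25	25	SLC24A2
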