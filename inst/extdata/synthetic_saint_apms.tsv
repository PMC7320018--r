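Bait	Prey	PreyGene	AvgSpec	FoldChange	BFDR
BAIT1	sp|PREY01_HUMAN	PREY01	47.3	7.33	0
BAIT1	sp|PREY02_HUMAN	PREY02	34.1	28.97	0
BAIT1	sp|PREY03_HUMAN	PREY03	32.4	23.04	0.125
BAIT1	sp|PREY04_HUMAN	PREY04	41.5	33.43	0.249
BAIT1	sp|PREY05_HUMAN	PREY05	23.8	35.95	0
BAIT1	sp|PREY06_HUMAN	PREY06	21.9	24.96	0.072
BAIT1	sp|PREY07_HUMAN	PREY07	19.7	35.12	0.169
BAIT1	sp|PREY08_HUMAN	PREY08	2.9	38.37	0.13
BAIT1	sp|PREY09_HUMAN	PREY09	9.2	10.17	0
BAIT1	sp|PREY10_HUMAN	PREY10	25.7	30.91	0.178
BAIT1	sp|PREY11_HUMAN	PREY11	51.5	37.9	0
BAIT1	sp|PREY12_HUMAN	PREY12	45	36.46	0.066
BAIT1	sp|PREY13_HUMAN	PREY13	15	15.2	0.223
BAIT1	sp|PREY14_HUMAN	PREY14	58.3	4.89	0.05
BAIT1	sp|PREY15_HUMAN	PREY15	43.6	6.51	0.053
BAIT1	sp|PREY16_HUMAN	PREY16	49.8	7.62	0
BAIT1	sp|PREY17_HUMAN	PREY17	25.4	30.54	0.272
BAIT1	sp|PREY18_HUMAN	PREY18	25.8	13.45	0
BAIT1	sp|PREY19_HUMAN	PREY19	57	32.8	0.2
BAIT1	sp|PREY20_HUMAN	PREY20	32.6	39.14	0.264
BAIT1	sp|PREY21_HUMAN	PREY21	26.2	5.94	0.245
BAIT1	sp|PREY22_HUMAN	PREY22	47.2	7.63	0.143
BAIT1	sp|PREY23_HUMAN	PREY23	13	22.77	0.195
BAIT1	sp|PREY24_HUMAN	PREY24	28.3	13.2	0.008
BAIT1	sp|PREY25_HUMAN	PREY25	18.4	20.69	0
BAIT1	sp|PREY26_HUMAN	PREY26	3.4	39.35	0.023
BAIT1	sp|PREY27_HUMAN	PREY27	30.7	29.26	0.011
BAIT1	sp|PREY28_HUMAN	PREY28	5.2	32.72	0.257
BAIT1	sp|PREY29_HUMAN	PREY29	6.4	20.53	0.168
BAIT1	sp|PREY30_HUMAN	PREY30	35.5	19.78	0.027
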