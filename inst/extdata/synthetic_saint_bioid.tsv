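Bait	Prey	PreyGene	AvgSpec	FoldChange	BFDR
BAIT1	sp|PREY03_HUMAN	PREY03	26.1	13.48	0
BAIT1	sp|PREY05_HUMAN	PREY05	3.1	23.86	0.064
BAIT1	sp|PREY08_HUMAN	PREY08	26	18.51	0.062
BAIT1	sp|PREY11_HUMAN	PREY11	16.2	11.67	0.048
BAIT1	sp|PREY21_HUMAN	PREY21	37.9	11.61	0
BAIT1	sp|PREY22_HUMAN	PREY22	31.3	4.89	0
BAIT1	sp|PREY23_HUMAN	PREY23	24.4	1.35	0
BAIT1	sp|PREY24_HUMAN	PREY24	21.9	18.94	0.197
BAIT1	sp|PREY25_HUMAN	PREY25	39.4	21.65	0.132
BAIT1	sp|PREY26_HUMAN	PREY26	34.9	21.96	0.057
BAIT1	sp|PREY27_HUMAN	PREY27	7.8	18.49	0
BAIT1	sp|PREY28_HUMAN	PREY28	13.8	14.32	0.172
BAIT1	sp|PREY29_HUMAN	PREY29	36.3	1.65	0.065
BAIT1	sp|PREY30_HUMAN	PREY30	24.9	7.73	0.061
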