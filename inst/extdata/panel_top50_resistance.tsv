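rank	probe_set_id	gene_symbol	r	p_value
1	J04456_at	LGALS1	0.541833	7.79E-06
2	D45917_s_at	TIMP3	0.540177	8.40E-06
3	U14394_at	TIMP3	0.5315	1.24E-05
4	M36341_at	ARF4	0.522613	1.84E-05
5	L14848_s_at	MICA	0.479438	0.000106
6	D12485_at	ENPP1	0.467591	0.000165
7	L19711_at	DAG1	0.431138	0.000584
8	X52599_at	NGF	0.427406	0.000659
9	M15059_at	FCER2	0.427116	0.000665
10	X53002_s_at	ITGB5	0.426866	0.000671
11	Z54367_s_at	PLEC	0.426377	0.000681
12	M55621_at	MGAT1	0.42595	0.000691
13	S67247_s_at	MYH10	0.423273	0.000753
14	Y08999_at	ARPC1A	0.422093	0.000782
15	D31762_at	TRAM2	0.417506	0.000904
16	X86809_at	PEA15	0.415101	0.000974
17	M14676_at	FYN	0.415045	0.000976
18	X83416_s_at	PRNP	0.412563	0.001054
19	M94345_at	CAPG	0.411344	0.001094
20	HG987-HT987_at	IGFBP7	0.407883	0.001217
21	Y00433_at	GPX1	0.405977	0.001289
22	L06419_at	PLOD1	0.402979	0.001411
23	M91670_at	UBE2S	0.399234	0.001578
24	J03040_at	SPARC	0.399167	0.001581
25	M36430_s_at	GNB1	0.396747	0.001699
26	U53204_at	PLEC	0.393282	0.00188
27	M24470_at	G6PD	0.393087	0.001891
28	M65085_at	FSHR	0.392808	0.001906
29	X93510_at	PDLIM4	0.39206	0.001948
30	X04828_at	GNAI2	0.387137	0.002245
31	M29277_s_at	MCAM	0.38412	0.002446
32	J04605_at	PEPD	0.383521	0.002488
33	X00351_f_at	ACTB	0.383294	0.002504
34	X12492_at	NFIC	0.382948	0.002528
35	X96719_at	CLEC2B	0.381127	0.002661
36	M13577_at	MBP	0.380867	0.002681
37	X68487_at	ADORA2B	0.37992	0.002753
38	X04412_at	GSN	0.379788	0.002763
39	M16279_at	CD99	0.379596	0.002778
40	M13194_at	ERCC1	0.379253	0.002805
41	U56244_at	TDRD9	0.37888	0.002834
42	HG2981-HT3125_s_at	CD44	0.377902	0.002912
43	D85433_at	COMMD1	0.377538	0.002942
44	U09937_rna1_s_at	PLAUR	0.376902	0.002994
45	Z19554_s_at	VIM	0.376885	0.002995
46	M28882_s_at	MCAM	0.375844	0.003083
47	U13220_at	FOXF2	0.371321	0.00349
48	HG2743-HT2846_s_at	CALD1	0.369192	0.003697
49	HG3395-HT3573_s_at	DNAJB2	0.369033	0.003713
50	X56494_at	PKM2	0.368555	0.003761
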