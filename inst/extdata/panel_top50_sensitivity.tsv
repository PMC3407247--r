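rank	probe_set_id	gene_symbol	r	p_value
1	U12595_at	TRAP1	-0.49975	4.80E-05
2	Z30425_at	NR1I3	-0.48648	8.11E-05
3	X64707_at	RPL13	-0.47666	0.000118
4	X04347_s_at	HNRNPA1	-0.46184	0.000204
5	D63874_at	HMGB1	-0.45152	0.000293
6	U70439_s_at	ANP32B	-0.44649	0.000349
7	AC002115_cds4_at	UPK1A	-0.43898	0.00045
8	M77140_at	GAL	-0.43825	0.000461
9	D50913_at	PMPCA	-0.42605	0.000689
10	D86964_at	DOCK2	-0.42394	0.000737
11	K02574_at	PNP	-0.42332	0.000752
12	Z14093_at	BCKDHA	-0.42137	0.0008
13	X69391_at	RPL6	-0.42075	0.000816
14	M36803_at	HPX	-0.41861	0.000873
15	D31763_at	ZNF33A	-0.41778	0.000896
16	HG4679-HT5104_at	RET	-0.41667	0.000928
17	X62534_s_at	HMGB2	-0.41589	0.000951
18	Z11850_at	GHR	-0.41516	0.000972
19	HG2365-HT2461_at	GAPDH	-0.41021	0.001133
20	X75091_s_at	SET	-0.41005	0.001139
21	M94046_at	MAZ	-0.40677	0.001259
22	HT3600_s_at	GCH1	-0.40592	0.001291
23	M84526_at	CFD	-0.40421	0.00136
24	X15940_at	RPL31	-0.4021	0.001449
25	L09708_at	C2	-0.39911	0.001584
26	D80004_at	KIAA0182	-0.39689	0.001691
27	M31523_at	TCF3	-0.39566	0.001754
28	U08471_at	FOLR3	-0.39234	0.001932
29	X73460_at	RPL3	-0.39144	0.001983
30	AF009674_at	AXIN1	-0.38879	0.002141
31	M55409_s_at	EEF1G	-0.38631	0.002298
32	L00058_at	MYC	-0.38337	0.002498
33	X80909_at	NACA	-0.38076	0.002689
34	M61827_rna1_s_at	SPN	-0.37897	0.002826
35	U12707_s_at	WAS	-0.37783	0.002918
36	X52056_at	SPI1	-0.3769	0.002994
37	X55733_at	EIF4B	-0.37578	0.003088
38	D80009_at	BMS1	-0.37494	0.003161
39	X55715_at	RPS3	-0.37273	0.003358
40	AC000061_cds3_at	CFTR	-0.37139	0.003483
41	X59303_s_at	VARS	-0.37021	0.003596
42	D87457_at	ELMO1	-0.36926	0.003691
43	X78136_at	PCBP2	-0.36801	0.003817
44	S82075_at	REV3L	-0.36684	0.003939
45	X67098_at	ENOSF1	-0.36678	0.003946
46	L28010_at	HNRNPF	-0.3656	0.004072
47	D86331_s_at	MMP15	-0.36408	0.004241
48	D21262_at	NOLC1	-0.36294	0.004371
49	L07540_at	RFC5	-0.36126	0.00457
50	Z47043_at	STARD9	-0.35925	0.004817
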