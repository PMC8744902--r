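Ks	Kg_a	subgroup_a	subgroup_index_a	protein_a	Kg_b	subgroup_b	subgroup_index_b	protein_b	Dab
1	25	d	1	CLEC3B	53	x	9	MMP-14	0.263109
2	22	u	18	GALNT3	46	x	2	p53	0.259298
3	13	u	9	C1QTNF3	50	x	6	PPAR-γ	0.225877
4	26	d	2	SCARA5	52	x	8	SNAIL1	0.219938
5	27	d	3	SLC10A6	50	x	6	PPAR-γ	0.214345
6	29	d	5	MYOC	54	x	10	Flotillin-1	0.200157
7	19	u	15	LAMA1	46	x	2	p53	0.199892
8	43	d	19	FMO2	47	x	3	ESR1	0.196550
9	29	d	5	MYOC	45	x	1	β-catenin	0.196394
10	39	d	15	GFRA1	45	x	1	β-catenin	0.184019
11	6	u	2	FGF21	46	x	2	p53	0.182339
12	20	u	16	RAPGEF4	45	x	1	β-catenin	0.182303
13	28	d	4	CXCL5	46	x	2	p53	0.181444
14	10	u	6	ADAMTS8	45	x	1	β-catenin	0.177848
15	42	d	18	PEG10	45	x	1	β-catenin	0.177726
16	35	d	11	HMGCS2	45	x	1	β-catenin	0.177443
17	15	u	11	IL11	45	x	1	β-catenin	0.177227
18	35	d	11	HMGCS2	46	x	2	p53	0.176906
19	21	u	17	DNER	45	x	1	β-catenin	0.176820
20	11	u	7	MEGF6	45	x	1	β-catenin	0.176612
21	36	d	12	LGI2	45	x	1	β-catenin	0.176606
22	7	u	3	TNFSF18	45	x	1	β-catenin	0.176603
23	41	d	17	IL1R2	45	x	1	β-catenin	0.176598
24	14	u	10	ANO4	45	x	1	β-catenin	0.176556
25	34	d	10	GPR88	45	x	1	β-catenin	0.176432
26	23	u	19	ACSBG1	45	x	1	β-catenin	0.176323
27	5	u	1	ADAMTS16	45	x	1	β-catenin	0.176315
28	12	u	8	SV2B	45	x	1	β-catenin	0.176264
29	17	u	13	HTR2B	45	x	1	β-catenin	0.176197
30	16	u	12	CDH10	45	x	1	β-catenin	0.176192
31	24	u	20	OLFM2	45	x	1	β-catenin	0.176038
32	32	d	8	SELENBP1	45	x	1	β-catenin	0.175939
33	33	d	9	FMO1	45	x	1	β-catenin	0.175776
34	33	d	9	FMO1	46	x	2	p53	0.175367
35	30	d	6	IFITM1	45	x	1	β-catenin	0.175056
36	44	d	20	COX4I2	45	x	1	β-catenin	0.174371
37	23	u	19	ACSBG1	46	x	2	p53	0.174167
38	34	d	10	GPR88	46	x	2	p53	0.173893
39	5	u	1	ADAMTS16	46	x	2	p53	0.173822
40	14	u	10	ANO4	46	x	2	p53	0.173770
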