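chrom	pos	ref	alt	rsid	gene	consequence	aa_change	cortex_expressed	varsome_class	disgenet_scz	maf_exac	maf_gnomad	maf_1000g	siphy	gerp_rs	gerp_nr	phylop100	phastcons100	sift_score	sift_call	polyphen2_score	polyphen2_call	mutassessor_score	mutassessor_call	metasvm_score	metasvm_call	metalr_score	metalr_call	vest3_score	fathmm_score	fathmm_call	lrt_score	lrt_call	muttaster_score	muttaster_call	rvis	rvis_percentile	loeuf
1	39914279	C	G	rs376728302	MACF1	missense	T-4642-S	yes	VUS	TRUE	0.000058	0.000092		20.393	5.95	5.95	7.818	1	1	T	0.589	P	0.345	N	-1.0558	T	0.0883	T	0.546	0.78	T	0.000008	D	1	D	-3.92	0.21	0.084
1	149907574	G	A	rs202234090	MTMR11	missense	P-56-L	yes	VUS	FALSE	0.000115	0.000159		12.986	4.68	4.68	3.916	1	0.02	D	0.932	P	2.045	M	0.2042	D	0.6049	D	0.568	-1.67	D			1	D			
2	136107663	T	C	rs183525970	ZRANB3	missense	Y-161-C	yes_low	VUS	FALSE	0.001391	0.001672	0.001374	15.459	5.42	5.42	6.253	1	0.001	D	1.0	D	3.255	M	1.0465	D	0.9121	D	0.857	-3.21	D	0	D	1	D			
2	219528732	C	T	rs138321594	RNF25	missense	R-443-Q	yes	VUS	FALSE	0.000069	0.000089		8.8576	3.74	5.55	1.989	0.99	0.005	D	0.223	B	0.895	L	-0.8015	T	0.1606	T	0.135	-0.21	T	0.020699	N	0.725	N			
3	102187900	A	G	rs145497598	ZPLD1	missense	K-301-R	yes_very_low	VUS	FALSE	0.000025	0.000021		15.196	5.28	5.28	5.352	1	0.358	T	0.004	B	0.345	N	-0.6888	T	0.2761	T	0.5	-1.34	T	0	D	1	D			
5	54721089	G	A	rs201703457	PPAP2A	missense	T-268-I	yes	VUS	FALSE	0.000016	0.000011		14.027	4.8	5.66	5.819	1	0.077	T	0.263	B	1.905	M	-1.0907	T	0.2078	T	0.406	1.5	T	0.018731	N	1	D			
5	175812257	G	A	rs35916027	NOP16	missense	R-120-C	yes	VUS	FALSE	0.004062	0.004068	0.005037	11.072	3.46	6.17	3.367	0.423	0	D	0.297	B	1.04	L	-1.0548	T	0.054	T	0.355			0.000101	N	0.999	N			
14	24709965	G	A	rs17102311	TINF2	missense	P-241-S	yes	VUS	FALSE	0.002158	0.002167	0.004121	8.383	3.46	4.36	1.43	0.942	0.013	D	1.0	D	2.045	M	0.1966	D	0.7489	D	0.172	-3.19	D	0.000159	N	1	D			
22	38061637	A	T	rs142028345	PDXP	missense	Y-217-F	yes	VUS	FALSE	0.007042	0.000004	0.005952	10.036	4.54	5.58	4.666	1	1	T	0.087	B	-0.715	N	-1.0489	T	0.0258	T	0.25	1.59	T			1	D			
1	23743859	T	C	rs192746462	TCEA3	missense	E-88-G	yes_low	likely_benign	FALSE	0.004760	0.004642	0.002289	11.332	5.02	5.02	1.69	1	0.25	T	0	B	0.695	N	-1.0688	T	0.0598	T	0.379			0.806532	N	0.992	N			
2	109382936	T	A	rs61748150	RANBP2	missense	S-1981-T	yes	benign	FALSE	0.008895	0.008229	0.006410	16.063	5.75	5.75	5.214	1	0.33	T	0.39	B	2.045	M	-1.0432	T	0.0603	T	0.16	1.56	T			0.964	N			
2	121748118	G	A	rs138987487	GLI2	missense	R-1543-H	yes_low	benign	TRUE	0.000502	0.000534	0.000916	18.456	4.98	4.98	9.657	1	0.054	T	1.0	D	1.89	L	-0.8456	T	0.1776	T	0.415	1.59	T	0.000001	D	1	D			
2	230723775	G	A		TRIP12	missense	S-205-L	yes	benign	FALSE	0.000025	0.000028		19.489	5.72	5.72	9.434	1	0.017	D	0.994	D	0.695	N	-0.833	T	0.1914	T	0.684	0.8	T	0	D	1	D			
4	39450295	G	A	rs143809363	KLB	missense	V-1042-I	yes_low	likely_benign	FALSE	0.003534	0.003275	0.000458	12.583	4.83	5.68	1.477	0.998	0.035	D	0.18	B	0.695	N	-1.0599	T	0.0642	T	0.125	1.67	T	0.442178	N	0.994	N			
9	79323853	C	T	rs200875180	PRUNE2	missense	D-1113-N	yes	likely_benign	FALSE	0.003781	0.003776	0.000916	14.954	5.94	5.94	4.165	0.984	0.0	D	1.0	D	0.975	L	-0.8847	T	0.2006	T	0.202	0.31	T	0.000385	D	1	D			
10	81925866	T	C	rs72807973	ANXA11	missense	I-278-V	yes	benign	FALSE	0.002990	0.003189	0.003205	9.0566	1.76	5.6	3.668	0.879	0.174	T	0.005	B	-0.98	N	-0.915	T	0.0034	T	0.171	4.06	T	0.011694	N	1	N			
15	94841610	G	A	rs149237812	MCTP2	missense	R-39-Q	yes_low	likely_benign	TRUE	0.001400	0.001199	0.000916	9.3437	3.19	5.13	1.658	0.044	0.166	T	0.024	B	0.46	N	-0.8817	T	0.1776	T	0.161	-0.66	T	0.22127	N	0.999	N			
2	238289767	T	C	rs112913396	COL6A3	missense	D-563-G	no	VUS	FALSE	0.002314	0.002079	0.000916	15.793	5.6	5.6	6.22	1	0.005	D	1.0	D	2.82	M	-0.202	T	0.3558	T	0.932	0.75	T	0.000042	D	1	D			
5	56777915	C	T	rs146468598	ACTBL2	missense	R-207-Q	no	VUS	FALSE	0.001820	0.002011	0.003205	15.631	4.91	4.91	7.645	0.989			0.461	P	3.37	M	0.7735	D	0.8058	D	0.785	-3.44	D	0.00001	D	0.999	D			
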