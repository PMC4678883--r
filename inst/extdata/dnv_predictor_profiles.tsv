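chrom	pos	ref	alt	gene	max_af	functional_class	sift	polyphen2_hdiv	polyphen2_hvar	lrt	mutation_taster	mutation_assessor	fathmm
1	22021668	A	G	USP48	.	missense	T	B;B;B;B	B;B;B;B	N	D	N	T;T
1	39827053	C	T	MACF1	.	missense	D	B;B;B;B	B;B;B;B	N	D	L	T;T;T;T;T;T
1	91844691	C	T	HFM1	.	missense	D	P;D;D	P;D;P	U	D	M	T;T
1	243319624	G	A	CEP170	.	missense	.	.	.	.	D	.	.
2	9650202	G	A	ADAM17	5.00E-04	missense	T	D;D	D;D	D	D	M	D
2	74758135	T	G	HTRA2	.	missense	D	D;D;D;D	D;D;D;D	D	D	M	D;D
2	179635385	T	C	TTN	.	missense	D	D;D;D;D;D	D;D;D;D;D	.	D	L	T;T;T;T;T
3	43121633	C	T	GTDC2	5.00E-04	missense	T	D	D	D	D	M	D;D
3	50211303	G	C	SEMA3F	.	missense	D	P;P	B;B	D	D	L	T;T;T;T;T;T
3	57335855	C	A	DNAH12	.	missense	.	.	.	.	N	H	.
3	119462963	C	T	MAATS1	3.83E-04	missense	D	D;D;D	D;D;D	D	D	M	T
6	132207739	C	G	ENPP1	.	missense	D	D	D	D	D	M	D
7	27140937	A	G	HOXA2	.	missense	D	D	D	D	D	H	D
7	28547270	G	T	CREB5	.	missense	D	D	D	D	D	M	T;T;T;T;T
7	121773654	C	T	AASS	.	missense	T	P	P	D	D	N	T;T
7	128658136	T	G	TNPO3	.	missense	D	D;D;D	D;D;D	D	D	M	T;T;T;T
7	143657109	G	A	OR2F1	.	missense	D	D	D	D	N	H	T
9	133952647	G	A	LAMC3	.	missense	T	D	P	N	N	L	T
9	139907507	G	A	ABCA2	1.23E-04	missense	T	B;B	B;B	U	N	N	D;D;D
9	140147394	C	T	C9orf173	.	missense	T	B;P;P;B	B;B;B;B	N	N	N	T;T
10	97763961	A	C	CC2D2B	.	missense	T	.	.	.	D	.	T
11	20119268	C	T	NAV2	.	missense	.	P;P;P;D	P;B;P;B	D	D	N	T;T;T;T;T;T;T;T
11	61277216	C	T	LRRC10B	.	missense	T	B	B	U	N	N	T
11	68370926	G	C	PPP6R3	.	missense	T	D;B;P;D;D;D;D;P	D;B;P;P;P;P;D;P	D	D	L	T;T;T;T;T;T;T;T;T;T;T
11	71943335	G	A	INPPL1	.	missense	T	D	D	D	D	M	T;T;T
11	73103282	G	A	RELT	.	missense	D	B	B	N	N	M	T;T
11	130319553	T	G	ADAMTS15	.	missense	D	P	P	.	D	L	T
12	21795009	G	A	LDHB	.	missense	D	P	P	N	D	H	D;D;D
12	57554800	A	G	LRP1	.	missense	T	D	D	D	D	M	D
12	111885301	C	T	SH2B3	.	missense	D	D;D;D	D;D;D	D	D	M	T;T
12	117187992	G	A	RNFT2	.	missense	T	P;P	B;B	D	D	L	T;T
12	122261146	G	C	SETD1B	.	missense	T	P	B	N	N	N	D;D
14	95590756	G	A	DICER1	.	missense	D	D	P	D	D	L	T;T;T;T;T
14	103465975	C	T	CDC42BPB	.	missense	D	P	P	D	D	L	T
15	45694835	G	A	SPATA5L1	.	missense	T	D	P	D	D	M	D
15	49584699	T	A	GALK2	.	missense	D	D;D	D;D	D	D	M	D;T;D
16	12798895	G	A	CPPED1	.	missense	D	D	D	D	D	M	D
16	89350182	T	C	ANKRD11	.	missense	T	B;B	B;B	N	D	L	T;T
17	67302892	T	C	ABCA5	.	missense	.	B;P	B;B	D	D	N	D;D
17	80146156	G	A	CCDC57	.	missense	T	D;D	D;D	D	D	M	T;T;T
1	152191073	C	T	HRNR	.	missense	T	B	B	.	N	N	T
6	42074959	C	T	C6orf132	.	missense	T	.	.	.	N	N	T
6	46660790	C	T	TDRD6	.	missense	T	B;B	B;B	N	N	L	T;T
11	60703710	CG	C	TMEM132A	.	frameshift	.	.	.	.	.	.	.
11	64084952	A	AC	TRMT112	.	frameshift	.	.	.	.	.	.	.
12	21175888	A	C	SLCO1B7	.	missense	T	B;B	B;B	N	N	N	T;T;T
20	3674309	C	T	SIGLEC1	0.009304	missense	T	B;B	B;B	N	N	N	T;T;T
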