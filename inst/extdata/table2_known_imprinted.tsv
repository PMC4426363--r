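gene	chrom	cb1_pct	cb1_mat	cb1_pat	cb2_pct	cb2_mat	cb2_pat	cb3_pct	cb3_mat	cb3_pat	bc1_pct	bc1_mat	bc1_pat	bc2_pct	bc2_mat	bc2_pat	bc3_pct	bc3_mat	bc3_pat	cbp	bcp	bias	snps	rpkm	lncrna
AK076687	chr2	5.3	10	180	4.5	26	557	0.4	2	551	1.1	2	185	1.8	5	269	0.7	3	439	5E-37	6E-62	P	226	1.03	TRUE
Sfmbt2	chr2	2.3	144	6233	8.4	790	8599	1.6	290	17804	1.0	79	7694	1.5	299	19439	1.0	217	22508	8E-31	2E-50	P	1092	78.8	FALSE
Nespas	chr2	0.0	0	94	0.0	0	251	2.2	5	223	0.0	0	88	4.0	8	191	0.6	1	161	4E-51	2E-30	P	34	2.58	TRUE
Phf17	chr3	32.4	665	1387	30.3	2099	4819	46.8	1568	1786	13.8	130	809	24.7	1483	4515	15.5	820	4457	2E-03	2E-18	P	321	48.2	FALSE
Sgce	chr6	4.5	11	231	8.8	78	809	6.6	47	666	2.9	4	135	6.3	60	890	3.7	33	870	1E-68	1E-52	P	319	19.9	FALSE
Peg10	chr6	0.1	18	12098	0.2	226	149701	0.3	310	123681	0.1	4	3763	0.3	507	150895	6.0	4951	78040	0E+00	4E-10	P	29	793	FALSE
Mest	chr6	0.0	0	16	1.7	3	175	0.3	11	3209	0.4	2	447	0.5	13	2780	1.1	71	6602	3E-117	4E-105	P	42	65.1	FALSE
Peg3	chr7	0.2	7	4413	0.1	21	24916	0.2	44	19674	0.5	17	3529	19.6	4032	16588	41.4	10215	14486	1E-302	2E-02	P	107	75.2	FALSE
Usp29	chr7	4.1	4	94	1.7	14	829	2.2	8	361	2.2	1	44	16.9	76	374	42.3	80	109	2E-87	4E-04	P	237	2.56	FALSE
D7ertd715e	chr7	0.0	0	86	0.0	0	313	0.0	0	243	0.0	0	95	1.1	2	176	0.0	0	78	4E-69	3E-37	P	64	5.96	TRUE
Snrpn	chr7	0.0	0	48	0.5	1	208	1.4	2	146	9.1	1	10	2.0	2	97	7.7	3	36	3E-45	2E-14	P	97	13.6	FALSE
H19	chr7	95.5	2508	119	95.4	8222	394	95.7	15727	714	98.8	61749	756	99.6	170049	742	51.3	173851	164950	7E-242	2E-03	M	9	2432	TRUE
Ascl2	chr7	92.6	50	4	89.9	519	58	86.1	352	57	100.0	10	0	81.6	476	107	96.2	101	4	1E-40	6E-08	M	4	13.6	FALSE
Cd81	chr7	67.0	254	125	90.3	1678	181	80.9	2438	576	72.3	225	86	79.5	2277	587	81.5	2043	465	8E-11	3E-17	M	74	87.8	FALSE
Tssc4	chr7	65.3	47	25	82.7	382	80	79.1	453	120	60.9	53	34	75.6	436	141	69.6	385	168	1E-14	2E-04	M	9	3.30	FALSE
Kcnq1ot1	chr7	0.2	1	544	0.2	2	1139	5.3	56	1010	0.3	1	349	0.5	3	580	0.0	0	305	9E-18	8E-87	P	371	0.99	TRUE
Cdkn1c	chr7	99.7	1185	3	100.0	9367	4	99.8	6716	13	100.0	351	0	76.5	6925	2123	99.9	2673	4	0E+00	9E-06	M	3	335	FALSE
Slc22a18	chr7	88.5	46	6	89.8	264	30	88.7	235	30	92.9	13	1	72.6	244	92	98.7	155	2	6E-33	2E-04	M	141	6.75	FALSE
Phlda2	chr7	100.0	120	0	100.0	4921	1	99.3	3279	24	95.7	112	5	72.2	3611	1392	98.7	1211	16	2E-55	1E-06	M	2	290	FALSE
Gab1	chr8	15.3	342	1896	18.3	1745	7809	14.8	1624	9329	9.2	129	1275	24.8	2367	7163	16.8	1575	7804	3.E-66	2.E-12	P	633	58.3	FALSE
Plagl1	chr10	0.0	0	86	0.4	2	528	1.0	2	202	0.0	0	19	1.3	4	297	4.2	4	91	4E-76	1E-27	P	142	1.15	FALSE
Grb10	chr11	68.8	1527	691	89.1	5640	692	85.0	5615	994	98.2	1849	33	92.0	8908	777	86.4	6314	994	5E-14	7E-12	M	455	159	FALSE
Zrsr1	chr11	0.0	0	131	0.4	1	225	0.4	1	273	0.0	0	33	21.4	69	254	1.9	6	312	4E-72	4E-08	P	7	4.86	FALSE
Grb10as	chr11	69.9	51	22	87.9	94	13	92.9	79	6	97.3	36	1	88.7	94	12	87.2	75	11	4E-08	1E-12	M	123	0.08	TRUE
Dlk1	chr12	100.0	2	0	99.5	195	1	93.1	297	22	100.0	2	0	93.8	45	3	98.1	53	1	2E-18	2E-10	P	15	1.47	FALSE
Meg3	chr12	99.3	438	3	70.0	7	3	97.6	290	7	99.9	1392	1	99.8	3325	5	99.9	11062	8	2E-69	6E-126	M	109	85.3	TRUE
Mirg	chr12	100.0	159	0	100.0	10	0	93.1	54	4	100.0	772	0	100.0	716	0	99.8	2007	4	1E-24	4E-150	M	119	11.4	TRUE
Pde10a	chr17	90.9	251	25	88.3	878	116	85.6	600	101	97.1	34	1	73.8	479	170	77.0	349	104	5E-64	1E-06	M	448	3.10	FALSE
Slc22a3	chr17	100.0	41	0	98.2	667	12	93.6	612	42	23.1	3	10	96.7	353	12	96.8	91	3	9E-40	1E-02	M	143	2.05	FALSE
Airn	chr17	4.3	28	628	0.4	19	5256	0.4	18	4213	1.6	6	370	1.4	47	3304	0.8	11	1362	2E-30	9E-124	P	443	3.01	TRUE
Igf2r	chr17	97.9	1011	22	98.6	2650	38	98.4	3821	63	97.8	723	16	98.6	3348	48	98.8	4743	57	1E-199	2E-111	M	330	73.0	FALSE
Igf2	chr7	45.8	2694	3186	32.5	22266	46340	29.0	20372	49913	8.2	71	790	46.9	17649	19980	75.9	24740	7869	1E-4	6E-1	NS	21	1418	FALSE
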