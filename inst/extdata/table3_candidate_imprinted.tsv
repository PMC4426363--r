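gene	chrom	start	end	strand	cb1_pct	cb1_mat	cb1_pat	cb2_pct	cb2_mat	cb2_pat	cb3_pct	cb3_mat	cb3_pat	bc1_pct	bc1_mat	bc1_pat	bc2_pct	bc2_mat	bc2_pat	bc3_pct	bc3_mat	bc3_pat	cbp	bcp	bias	snps	rpkm	lncrna
Id1	chr2	152562009	152563146	+	43.1	31	41	33.5	52	103	35.3	55	101	35.2	32	59	35.5	39	71	15.4	14	77	2.E-02	9.E-04	P	4	16.0	FALSE
R74862	chr7	150207688	150239273	-	65.8	25	13	87.7	71	10	82.5	99	21	58.3	21	15	72.4	63	24	72.0	67	26	1.E-07	1.E-02	M	98	0.27	TRUE
Tsci1	chr8	83383307	83405773	+	0.0	0	41	0.7	1	148	0.7	1	143	0.0	0	40	12.5	10	70	9.5	13	124	3.E-40	3.E-15	P	82	0.16	TRUE
Tsci2	chr11	12051323	12097365	+	57.6	19	14	85.7	48	8	77.1	37	11	95.5	21	1	93.5	87	6	97.9	93	2	8.E-04	1.E-16	M	75	0.08	TRUE
AK017220	chr11	51003334	51033915	-	3.6	6	159	2.2	3	134	0.7	1	137	4.8	4	79	56.3	117	91	7.2	15	192	3.E-44	4.E-03	P	161	2.10	FALSE
Tsci3	chr11	51033968	51061895	+	3.9	5	123	3.1	9	280	0.3	1	285	4.4	2	43	46.9	207	234	9.6	42	396	7.E-54	4.E-04	P	101	0.32	FALSE
AK010368	chr11	97459824	97484207	+	0.7	1	133	1.5	6	407	0.7	3	451	1.5	1	64	37.0	101	172	47.4	451	500	5.E-92	3.E-02	P	150	4.40	TRUE
Tsci4	chr12	82108796	82120245	-	5.6	1	17	0.0	0	40	0.0	0	45	0.0	0	10	15.4	2	11	48.3	14	15	3.E-17	5.E-02	P	52	0.04	TRUE
Tsci5	chr12	110730857	110753078	-	100.0	2	0	100.0	8	0	100.0	16	0	100.0	6	0	100.0	12	0	100.0	34	0	2.E-07	1.E-10	M	35	0.03	TRUE
Pdgfb	chr15	79826305	79845238	-	41.3	250	356	42.2	1999	2737	38.6	2126	3380	27.9	58	150	48.8	2928	3070	44.2	3471	4375	6.E-03	4.E-02	P	97	62.3	FALSE
Tsci6	chr15	96980667	96997795	-	7.8	17	200	19.7	12	49	3.5	12	333	0.3	1	386	0.9	6	662	0.9	9	1032	8.E-18	5.E-103	P	129	0.75	TRUE
1700010i14rik	chr17	9181197	9201184	+	100.0	18	0	84.0	21	4	90.7	39	4	100.0	9	0	100.0	33	0	70.1	47	20	8.E-11	2.E-03	M	43	0.81	FALSE
Qk	chr17	10399335	10512226	-	55.2	235	191	56.4	648	501	55.2	574	465	70.2	342	145	64.3	687	381	63.9	565	319	7.E-03	1.E-04	M	176	36.2	FALSE
Pacrg	chr17	10595877	11033057	-	75.0	3	1	92.9	13	1	86.7	13	2	100.0	5	0	90.0	9	1	84.6	11	2	1.E-04	9.E-04	M	29	0.21	FALSE
Park2	chr17	11033249	12256226	+	86.8	105	16	81.3	74	17	85.7	60	10	61.1	33	21	76.5	78	24	73.6	53	19	9.E-18	3.E-03	M	273	0.08	FALSE
Mas1	chr17	13033870	13061009	-	100.0	6	0	100.0	63	0	99.2	123	1	100.0	2	0	100.0	34	0	100.0	12	0	2.E-27	4.E-10	M	55	0.27	FALSE
Dact2	chr17	14332236	14340838	-	59.6	56	38	56.9	357	270	54.5	486	405	83.2	84	17	71.4	401	161	70.8	685	283	3.E-03	6.E-07	M	40	7.65	FALSE
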