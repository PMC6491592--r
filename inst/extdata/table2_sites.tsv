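gene	site	aa_index	nt_index_printed	position_printed	codon_pos	codon_before	codon_after	aa_before_printed	aa_after_printed	conversion	coverage	count_ref	count_alt	printed_pct_ref	printed_pct_alt	synonymous_flag_printed
rbcL	1	50	150	50/150	3	CCC	CCU	P	P	C-to-U	188389	39	187680	0.02	99.62	TRUE
matK	1	160	478	160/478	1	CAU	UAU	H	Y	C-to-U	751	195	556	26.1	73.9	FALSE
matK	2	245	734	245/734	2	UCU	UUU	S	F	C-to-U	3612	1888	1718	52.3	47.6	FALSE
psbA	1	232	696	232/696	3	UCC	UCU	S	S	C-to-U	2011054	387	2002141	0.02	99.56	TRUE
atpA	1	258	774	258/774	2	UCA	UUA	S	L	C-to-U	2684	37	2646	1.4	98.5	FALSE
atpA	2	383	1148	383/1148	2	UCA	UUA	S	L	C-to-U	3878	51	3821	1.3	98.5	FALSE
atpF	1	31	92	31/92	2	CCA	CUA	P	L	C-to-U	3913	331	3579	8.5	91.4	FALSE
atpI	1	15	45	15/45	3	UAC	UAU	Y	Y	C-to-U	3682	2736	940	74.3	25.5	FALSE
atpI	2	210	629	210/629	2	UCA	UUA	S	L	C-to-U	3580	47	3528	1.3	98.5	FALSE
rpoC2	1	1235	3704	1235/3704	2	UCA	UUA	S	L	C-to-U	493	43	451	8.7	91.3	FALSE
rpoC1	1	14	41	14/41	2	CCA	CUA	P	L	C-to-U	764	203	558	26.5	72.9	FALSE
rpoC1	2	61	182	61/182	2	UCC	UUC	S	F	C-to-U	1004	543	462	54	46	FALSE
rpoC1	3	107	321	107/321	3	AUC	AUU	I	I	C-to-U	818	487	331	59.5	40.4	TRUE
rpoC1	4	178	500	178/500	2	UCA	UUA	S	L	C-to-U	848	98	750	11.5	88.3	FALSE
rpoC1	5	210	629	210/629	2	UCA	UUA	S	L	C-to-U	857	149	709	17.4	82.6	FALSE
rpoC1	6	267	799	267/799	1	CGG	UGG	R	W	C-to-U	906	43	859	4.7	94.7	FALSE
rpoB	1	29	10	29-10	2	UCC	UUC	S	F	C-to-U	223	81	142	36.2	63.4	FALSE
rpoB	2	113	338	113/338	2	UCU	UUU	S	F	C-to-U	205	82	123	39.8	59.7	FALSE
rpoB	3	184	551	184/551	2	UCA	UUA	S	F	C-to-U	78	66	13	83.5	16.5	FALSE
rpoB	4	189	566	189/566	2	UCA	UUA	S	F	C-to-U	112	54	59	47.8	52.2	FALSE
rpoB	5	665	1994	665/1994	2	UCA	UUU	S	F	C-to-U	233	11	223	4.7	95.3	FALSE
rpoB	6	807	2420	807/2420	2	UCA	UUA	S	F	C-to-U	230	31	200	13.4	86.6	FALSE
rpoB	7	900	2698	900/2698	1	CCU	UCU	P	S	C-to-U	286	75	212	26.1	73.9	FALSE
psbZ	1	17	50	17/50	2	UCA	UUA	S	L	C-to-U	23558	869	22664	3.7	96.2	FALSE
psbZ	2	60	180	60/180	3	CUC	CUU	L	L	C-to-U	15389	14560	810	94.6	5.3	TRUE
rps14	1	27	80	27/80	2	UCA	UUA	S	L	C-to-U	14988	470	14472	3.1	96.6	FALSE
psaA	1	51	153	51/153	3	GCC	GCU	A	A	C-to-U	10434	6	10407	0.1	99.7	TRUE
ycf3	1	15	44	15/44	2	UCU	UUU	S	F	C-to-U	2070	694	1372	33.5	66.2	FALSE
ycf3	2	21	63	21/63	3	AUC	AUU	I	I	C-to-U	1477	640	834	43.3	56.4	TRUE
ycf3	3	62	185	62/185	2	ACG	AUG	T	M	C-to-U	648	502	146	77.3	22.5	FALSE
ycf3	4	64	191	64/191	2	CCA	CUA	P	L	C-to-U	903	423	469	46.8	51.9	FALSE
ndhJ	1	43	128	43/128	2	UCA	UUA	S	L	C-to-U	968	245	724	25.3	74.7	FALSE
ndhK	1	23	69	23/69	3	CCC	CCU	P	P	C-to-U	264	155	110	58.5	41.5	TRUE
ndhK	2	27	81	27/81	3	UUC	UUU	F	F	C-to-U	343	191	153	55.5	44.5	TRUE
ndhC	1	13	5	13-5	1	CAC	UAC	H	Y	C-to-U	335	69	267	20.5	79.5	FALSE
ndhC	2	104	311	104/311	2	CCA	CUA	P	L	C-to-U	264	155	110	58.5	41.5	FALSE
ndhC	3	108	323	108/323	2	UCA	UUA	S	L	C-to-U	343	191	153	55.5	44.5	FALSE
atpB	1	395	1184	395/1184	2	UCA	UUA	S	L	C-to-U	8704	140	8556	1.6	98.3	FALSE
accD	1	452	1355	452/1355	2	UCA	UUA	S	L	C-to-U	625	224	393	35.8	62.8	FALSE
accD	2	466	1397	466/1397	2	UCC	UUC	P	L	C-to-U	574	245	329	42.6	57.2	FALSE
psaI	1	25	74	25/74	2	UCU	UUU	S	F	C-to-U	1721	579	1140	33.6	66.2	FALSE
psaI	2	27	80	27/80	1	CAU	UAU	H	Y	C-to-U	1152	1078	72	93.5	6.2	FALSE
psaI	3	34	102	34/102	3	GUC	GUU	V	V	C-to-U	3243	2758	482	85	14.9	FALSE
ycf4	1	176	528	176/528	3	UUC	UUU	F	F	C-to-U	2311	1774	538	76.7	23.3	TRUE
psbJ	1	20	59	20/59	2	CCU	CUU	P	L	C-to-U	21133	392	20673	1.9	97.8	FALSE
psbF	1	26	77	26/77	2	UCU	UUU	S	F	C-to-U	8436	252	8177	3	96.9	FALSE
psbE	1	72	214	72/214	1	CCU	UCU	P	S	C-to-U	13182	145	13023	1.1	98.8	FALSE
petL	1	2	5	2/5	2	UCU	UUU	S	F	C-to-U	2646	559	2084	21.1	78.7	FALSE
petL	2	19	56	19/56	2	CCA	CUA	P	L	C-to-U	1591	48	1540	3	96.7	FALSE
rps18	1	74	221	74/221	2	UCG	UUG	S	L	C-to-U	5264	283	4975	5.4	94.5	FALSE
clpP	1	26	82	26/82	1	CAU	UAU	H	Y	C-to-U	865	110	756	12.7	87.3	FALSE
clpP	2	187	559	187/559	1	CAU	UAU	H	Y	C-to-U	1533	107	1402	5.4	91.4	FALSE
psbN	1	10	30	10/30	3	UUC	UUU	F	F	C-to-U	57622	12298	45238	21.3	78.5	TRUE
petB	1	4	11	4/11	2	AAU	AGU	N	S	A-to-G	10646	8356	2268	78.5	21.3	FALSE
petB	2	142	424	142/424	1	CGG	UGG	R	W	C-to-U	27257	290	26917	1.1	98.7	FALSE
petB	3	206	617	206/617	2	CCA	CUA	P	L	C-to-U	9585	220	9351	2.3	97.5	FALSE
petD	1	162	484	162/484	1	CAA	UAA	Q	stop	C-to-U	13552	248	13286	1.8	98	FALSE
rpoA	1	67	200	67/200	2	UCU	UUU	S	F	C-to-U	947	323	622	34.1	65.6	FALSE
rpoA	2	123	368	123/368	2	UCA	UUA	S	L	C-to-U	1193	254	938	21.3	78.6	FALSE
rpl36	1	14	5	14-5	2	GUU	GCU	V	A	U-to-C	3479	2	3475	0.1	99.8	FALSE
rps3	1	157	470	157/470	2	ACA	AUA	T	I	C-to-U	1513	74	1440	4.9	95.1	FALSE
rps3	2	195	583	195/583	1	CAU	UAU	H	Y	C-to-U	1951	309	1638	15.8	83.9	FALSE
rpl2	1	1	2	1/2	2	ACG	AUG	T	M	C-to-U	708	340	369	48	52	FALSE
rpl23	1	24	71	24/71	2	UCU	UUU	S	F	C-to-U	562	84	479	48	85.1	FALSE
ndhB	1	50	149	50/149	2	UCA	UUA	S	L	C-to-U	803	88	716	10.9	89.1	FALSE
ndhB	2	156	467	156/467	2	CCA	CUA	P	L	C-to-U	929	41	887	4.4	95.4	FALSE
ndhB	3	181	542	181/542	2	ACG	AUG	T	M	C-to-U	536	55	482	10.2	89.8	FALSE
ndhB	4	204	611	204/611	2	UCA	UUA	S	L	C-to-U	343	58	286	16.9	83.1	FALSE
ndhB	5	205	704	205/704	2	UCC	UUC	S	F	C-to-U	347	53	295	15.2	84.8	FALSE
ndhB	6	246	737	246/737	2	CCA	CUA	P	L	C-to-U	167	65	102	38.7	60.7	FALSE
ndhB	7	277	830	277/830	2	UCA	UUA	S	L	C-to-U	193	123	71	61.3	36.4	FALSE
ndhB	8	279	836	279/836	2	UCA	UUA	S	L	C-to-U	162	80	83	49.1	50.9	FALSE
ndhB	9	371	112	371/112	2	UCA	UUA	S	L	C-to-U	1134	108	1025	9.5	90.3	FALSE
ndhB	10	494	1481	494/1481	2	CCA	CUA	P	L	C-to-U	1271	188	1082	14.8	85.1	FALSE
ndhF	1	21	62	21/62	2	UCA	UUA	S	L	C-to-U	674	46	628	6.8	93	FALSE
ndhF	2	87	259	87/259	1	CAC	UAC	H	Y	C-to-U	208	51	158	24.4	75.6	FALSE
ndhF	3	131	392	131/392	2	UCU	UUU	S	F	C-to-U	1205	13	1191	11.1	98.8	FALSE
ccsA	1	118	353	118/353	2	UCA	UUA	S	L	C-to-U	750	70	680	9.3	90.5	FALSE
ccsA	2	272	815	272/815	2	UCA	UUA	S	L	C-to-U	731	68	662	9.3	90.4	FALSE
ndhD	1	1	2	1/2	2	ACG	AUG	T	M	C-to-U	791	285	505	36	63.8	FALSE
ndhD	2	22	65	22/65	2	UCC	UUC	S	F	C-to-U	628	82	545	13	86.6	FALSE
ndhD	3	130	389	130/389	2	UCA	UUA	S	L	C-to-U	722	129	593	17.8	82	FALSE
ndhD	4	227	680	227/680	2	UCG	UUG	S	L	C-to-U	840	190	648	22.6	77.1	FALSE
ndhD	5	318	953	318/953	2	ACA	AUA	T	I	C-to-U	930	124	803	13.3	86.3	FALSE
ndhG	1	17	50	17/50	2	UCA	UUA	S	L	C-to-U	531	115	417	21.6	78.4	FALSE
ndhG	2	116	347	116/347	2	CCG	CUG	P	L	C-to-U	1198	107	1088	8.9	90.7	FALSE
ndhA	1	358	1073	358/1073	2	UCC	UUC	S	F	C-to-U	1467	198	1226	13.5	86.2	FALSE
ndhH	1	30	10	30-10	3	CUC	CUU	L	L	C-to-U	1107	1020	85	92.1	7.7	TRUE
ndhH	2	169	505	169/505	1	CAU	UAU	H	Y	C-to-U	740	85	651	11.5	87.9	FALSE
rrn5S	1	NA	72	-/72	NA	NA	NA	NA	NA	C-to-U	9350	24	9258	0.3	99	FALSE
rrn23S	1	NA	1327	-/1327	NA	NA	NA	NA	NA	U-to-C	2532	381	2148	15	84.8	FALSE
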