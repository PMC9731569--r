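tool	threshold_label	n_pv	tp	fn	fp	tn
BayesDel_addAF	>=0.39	531	250	164	22	95
CADD	>10.44	886	655	39	101	91
ClinPred	>0.95	481	265	99	43	74
Condel	>0.3	481	331	33	76	41
DANN	>0.96	531	372	42	71	46
Eigen-PC	>1.87	531	329	85	35	82
FATHMM	<=-3.39	481	150	214	23	94
fathmm-MKL	>0.7	531	328	86	39	78
GERP++	>3.49	531	248	166	26	91
integrated_fitCons	>0.05	531	414	1	117	1
LIST-S2	>=0.75	344	246	28	39	31
LRT	<0.3	270	169	7	84	10
MetaLR_score	>0.8	481	251	113	42	75
MetaSVM_score	>0.6	481	260	104	39	78
MutationAssessor	>2.53	359	249	36	41	33
MutationTaster	>0.95	531	386	28	102	15
MutPred	>0.5	467	343	12	96	16
phastCons17way	>0.17	531	357	57	57	60
phastCons30way	>0.28	531	329	85	51	66
phyloP100way	>0.42	531	349	65	56	61
phyloP30way	>0.51	531	307	107	63	54
PolyPhen-2	>0.65	481	243	121	37	80
PROVEAN	<=-1.03	481	358	6	106	11
REVEL	>0.65	481	294	70	46	71
SIFT	<0.1	481	325	39	74	43
SiPhy_29way	>10.62	531	233	181	33	84
VEST4	>0.7	531	273	141	33	84
ada	>0.5	56	47	3	1	5
MaxEntScan	Diff>2&Per>5	54	50	2	1	2
rf	>0.6	56	47	3	1	5
SpliceAI	>0.65	663	35	23	1	604
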