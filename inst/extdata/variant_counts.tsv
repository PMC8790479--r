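disorder	gene	transcript	variant_c	variant_p	classification	count	rel_freq	total_freq
PCD	SLC22A5	NM_003060.4	c.1400C>G	p.S467C	P	9	24.32	7.63
PCD	SLC22A5	NM_003060.4	c.51C>G	p.F17L	VUS	8	21.62	6.78
PCD	SLC22A5	NM_003060.4	c.760C>T	p.R254X	P	6	16.22	5.08
PCD	SLC22A5	NM_003060.4	c.1195C>T	p.R399W	P	2	5.41	1.69
PCD	SLC22A5	NM_003060.4	c.338G>A	p.C113Y	P	2	5.41	1.69
PCD	SLC22A5	NM_003060.4	c.1108G>A	p.G370R	VUS	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.1196G>A	p.R399Q	P	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.428C>T	p.P143L	LP	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.431T>C	p.L144P	VUS	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.470C>T	p.S157F	VUS	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.497+1G>T	-	P	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.621G>T	p.Q207H	LP	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.653-8T>A	-	VUS	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.782_799del	p.V261_P266del	VUS	1	2.70	0.85
PCD	SLC22A5	NM_003060.4	c.845G>A	p.R282Q	P	1	2.70	0.85
PAHD	PAH	NM_000277.3	c.158G>A	p.R53H	VUS	3	12.50	2.54
PAHD	PAH	NM_000277.3	c.1068C>A	p.Y356*	P	2	8.33	1.69
PAHD	PAH	NM_000277.3	c.498C>G	p.Y166*	P	2	8.33	1.69
PAHD	PAH	NM_000277.3	c.611A>G	p.Y204C	LP	2	8.33	1.69
PAHD	PAH	NM_000277.3	c.721C>T	p.R241C	P	2	8.33	1.69
PAHD	PAH	NM_000277.3	c.728G>A	p.R243Q	P	2	8.33	1.69
PAHD	PAH	NM_000277.3	c.208_210delTCT	p.S70del	P	1	4.17	0.85
PAHD	PAH	NM_000277.3	c.284_286del	p.I95del	P	1	4.17	0.85
PAHD	PAH	NM_000277.3	c.331C>T	p.R111*	P	1	4.17	0.85
PAHD	PAH	NM_000277.3	c.353-6T>C	-	P	1	4.17	0.85
PAHD	PAH	NM_000277.3	c.464G>A	p.R155H	P	1	4.17	0.85
PAHD	PAH	NM_000277.3	c.527G>A	p.R176Q	LP	1	4.17	0.85
PAHD	PAH	NM_000277.3	c.907del	p.S303Pfs*38	P	1	4.17	0.85
BH4D	PTS	NM_000317.3	c.4A>C	p.S2R	P	1	4.17	0.85
BH4D	PTS	NM_000317.3	c.259C>T	p.P87S	P	1	4.17	0.85
BH4D	PTS	NM_000317.3	c.84-291A>G	-	P	1	4.17	0.85
BH4D	PTS	NM_000317.3	c.286G>A	p.D96N	P	1	4.17	0.85
SCADD	ACADS	NM_000017.4	c.1031A>G	p.E344G	P	3	23.08	2.54
SCADD	ACADS	NM_000017.4	c.578C>T	p.S193L	VUS	2	15.38	1.69
SCADD	ACADS	NM_000017.4	c.413delA	p.N138Mfs*36	P	2	15.38	1.69
SCADD	ACADS	NM_000017.4	c.1130C>T	p.P377L	LP	1	7.69	0.85
SCADD	ACADS	NM_000017.4	c.795+1G>A	-	LP	1	7.69	0.85
SCADD	ACADS	NM_000017.4	c.758T>G	p.V253G	US	1	7.69	0.85
SCADD	ACADS	NM_000017.4	c.172C>T	p.R58*	LP	1	7.69	0.85
SCADD	ACADS	NM_000017.4	c.286G>A	p.G96S	LP	1	7.69	0.85
SCADD	ACADS	NM_000017.4	c.220C>T	p.P74S	LP	1	7.69	0.85
CD	SLC25A13	NM_014251.2	c.852_855delTATG	p.M285Pfs*2	P	4	44.44	3.39
CD	SLC25A13	NM_014251.2	IVS16ins3kb	p.A584Vfs*2	P	2	22.22	1.69
CD	SLC25A13	NM_014251.2	c.1048G>A	p.D350N	VUS	1	11.11	0.85
CD	SLC25A13	NM_014251.2	c.1638_1660dup23	p.A554Gfs*17	P	1	11.11	0.85
CD	SLC25A13	NM_014251.2	c.1750_1751ins3kb	-	P	1	11.11	0.85
MCC3	MCCC2	NM_022132.4	c.1103delG	p.G368Vfs*70	LP	1	16.67	0.85
MCC3	MCCC2	NM_022132.4	c.1550G>A	p.G517E	VUS	1	16.67	0.85
MCC3	MCCC2	NM_022132.4	c.1061C>T	p.T354l	VUS	1	16.67	0.85
MCC3	MCCC2	NM_022132.4	c.1599T>A	p.D533E	VUS	1	16.67	0.85
MCC3	MCCC2	NM_022132.4	c.730C>G	p.P244A	VUS	1	16.67	0.85
MCC3	MCCC2	NM_022132.4	c.1144_1147inv	p.K382_K383delinsF*	P	1	16.67	0.85
IVA	IVD	NM_002225.5	c.158G>C	p.Arg53Pro	P	1	20.00	0.85
IVA	IVD	NM_002225.5	c.349G>A	p.Glu117Lys	VUS	1	20.00	0.85
IVA	IVD	NM_002225.5	c.214G>A	p.D72N	VUS	1	20.00	0.85
IVA	IVD	NM_002225.5	c.631A>G	p.T211A	LP	1	20.00	0.85
IVA	IVD	NM_002225.5	c.865G>A	p.G289R	LP	1	20.00	0.85
CIT1	ASS1	NM_000050.4	c.1087C>T	p.R363W	P	2	50.00	1.69
CIT1	ASS1	NM_000050.4	c.748C>T	p.L250F	VUS	1	25.00	0.85
CIT1	ASS1	NM_000050.4	c.11A>G	p.K4R	VUS	1	25.00	0.85
MBD2	ACADSB	NM_001609.3	c.1165A>G	p.M389V	P	3	100.00	2.54
VLCADD	ACADVL	NM_000018.4	c.621_622+9del	-	P	1	33.33	0.85
VLCADD	ACADVL	NM_000018.4	c.622+14del	-	VUS	1	33.33	0.85
VLCADD	ACADVL	NM_000018.4	c.1531C>T	p.R511W	LP	1	33.33	0.85
MADD	ETFB	NM_001985.2	c.340_342del	p.Lys114del	VUS	1	33.33	0.85
MADD	ETFB	NM_001985.2	c.253C>T	p.Arg85Ter	P	1	33.33	0.85
MADD	ETFB	NM_001985.2	c.82G>A	p.Gly28Ser	VUS	1	33.33	0.85
HMET	MAT1A	NM_000429.3	c.755T>C	p.I252T	LP	1	33.33	0.85
HMET	MAT1A	NM_000429.3	c.314A>T	p.N105I	VUS	1	33.33	0.85
HMET	MAT1A	NM_000429.3	c.386A>G	p.D129G	VUS	1	33.33	0.85
GA1	GCDH	NM_000159.3	c.532G>A	p.G178R	P	1	50.00	0.85
GA1	GCDH	NM_000159.3	c.1244-2A>C	-	P	1	50.00	0.85
PA	PCCA	NM_000282.4	c.819+1G>A	-	LP	1	50.00	0.85
PA	PCCA	NM_000282.4	c.1850T>C	p.L617P	VUS	1	50.00	0.85
TYR3	HPD	NM_002150.2	c.893A>C	p.Q298P	VUS	1	50.00	0.85
TYR3	HPD	NM_002150.2	c.217T>C	p.S73P	VUS	1	50.00	0.85
MGA3	SERAC1	NM_032861.3	c.1364C>G	p.T455S	VUS	1	100.00	0.85
NKH	GLDC	NM_000170.2	c.2405C_T	p.A802v	P	1	100.00	0.85
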