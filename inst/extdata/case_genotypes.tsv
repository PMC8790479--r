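case_id	gene	allele1_c	allele1_p	allele2_c	allele2_p	allele3_c	allele3_p
AA01	PTS	c.84-291A>G	-	c.286G>A	p.D96N	-	-
AA02	PTS	c.4A>C	p.S2R	c.259C>T	p.P87S	-	-
AA03	PAH	c.611A>G	p.Y204C	c.158G>A	p.R53H	-	-
AA04	PAH	c.728G>A	p.R243Q	c.158G>A	p.R53H	-	-
AA05	PAH	c.721C>T	p.R241C	-	-	-	-
AA06	PAH	c.208_210delTCT	p.S70del	c.353-6T>C	-	-	-
AA07	PAH	c.1068C>A	p.Y356*	c.907del	p.S303Pfs*38	-	-
AA08	PAH	c.611A>G	p.Y204C	c.728G>A	p.R243Q	-	-
AA09	PAH	c.527G>A	p.R176Q	c.498C>G	p.Y166*	-	-
AA10	PAH	c.1068C>A	p.Y356*	c.158G>A	p.R53H	-	-
AA11	PAH	c.721C>T	p.R241C	c.284_286delTCA	p.I95del	-	-
AA12	PAH	c.464G>A	p.R155H	c.331C>T	p.R111*	-	-
AA13	MAT1A	c.755T>C	p.I252T	-	-	-	-
AA14	MAT1A	c.314A>T	p.N105I	c.386A>G	p.D129G	-	-
AA15	HPD	c.893A>C	p.Q298P	c.217T>C	p.S73P	-	-
AA16	ASS1	c.1087C>T	p.R363W	c.748C>T	p.L250F	-	-
AA17	ASS1	c.1087C>T	p.R363W	c.11A>G	p.K4R	-	-
AA18	SLC25A13	c.1048G>A	p.D350N	IVS16ins3kb	p.A584Vfs*2	-	-
AA19	SLC25A13	IVS16ins3kb	p.A584Vfs*2	c.852_855delTATG	p.M285Pfs*2	-	-
AA20	SLC25A13	c.852_855delTATG	p.M285Pfs*2	-	-	-	-
AA21	SLC25A13	c.852_855delTATG	p.M285Pfs*2	c.1638_1660dup23	p.A554Gfs*17	-	-
AA22	SLC25A13	c.852_855delTATG	p.M285Pfs*2	c.1750_1751ins3kb	-	-	-
OA01	MCCC2	c.730C>G	p.P244A	c.1144_1147inv	p.K382_K383delinsF*	-	-
OA02	MCCC2	c.1103delG	p.G368Vfs*70	c.1550G>A	p.G517E	-	-
OA03	MCCC2	c.1061C>T	p.T354l	c.1599T>A	p.D533E	-	-
OA04	ACADSB	c.1165A>G	p.M389V	-	-	-	-
OA05	ACADSB	c.1165A>G	p.M389V	-	-	-	-
OA06	ACADSB	c.1165A>G	p.M389V	-	-	-	-
OA07	PCCA	c.819+1G>A	-	c.1850T>C	p.L617P	-	-
OA08	GCDH	c.532G>A	p.G178R	c.1244-2A>C	-	-	-
OA09	IVD	c.158G>C	p.Arg53Pro	c.349G>A	p.Glu117Lys	-	-
OA10	IVD	c.631A>G	p.T211A	c.865G>A	p.G289R	-	-
FA01	SLC22A5	c.1400C>G	p.S467C	c.428C>T	p.P143L	-	-
FA02	SLC22A5	c.51C>G	p.F17L	-	-	-	-
FA03	SLC22A5	c.760C>T	p.R254X	c.1400C>G	p.S467C	-	-
FA04	SLC22A5	c.497+1G>T	-	-	-	-	-
FA05	SLC22A5	c.1400C>G	p.S467C	-	-	-	-
FA06	SLC22A5	c.51C>G	p.F17L	c.621G>T	p.Q207H	-	-
FA07	SLC22A5	c.431T>C	p.L144P	c.1195C>T	p.R399W	-	-
FA08	SLC22A5	c.51C>G	p.F17L	c.338G>A	p.C113Y	-	-
FA09	SLC22A5	c.1195C>T	p.R399W	c.1400C>G	p.S467C	-	-
FA10	SLC22A5	c.1400C>G	p.S467C	c.1196G>A	p.R399Q	-	-
FA11	SLC22A5	c.51C>G	p.F17L	c.470C>T	p.S157F	-	-
FA12	SLC22A5	c.338G>A	p.C113Y	-	-	-	-
FA13	SLC22A5	c.1108G>A	p.G370R	c.51C>G	p.F17L	-	-
FA14	SLC22A5	c.760C>T	p.R254X	-	-	-	-
FA15	SLC22A5	c.51C>G	p.F17L	c.782_799del	p.V261_P266del	-	-
FA16	SLC22A5	c.760C>T	p.R254X	c.845G>A	p.R282Q	-	-
FA17	SLC22A5	c.1400C>G	p.S467C	-	-	-	-
FA18	SLC22A5	c.760C>T	p.R254X	c.1400C>G	p.S467C	-	-
FA19	SLC22A5	c.760C>T	p.R254X	c.1400C>G	p.S467C	-	-
FA20	SLC22A5	c.51C>G	p.F17L	c.653-8T>A	-	-	-
FA21	SLC22A5	c.51C>G	p.F17L	-	-	-	-
FA22	SLC22A5	c.760C>T	p.R254X	-	-	-	-
FA23	ACADVL	c.621_622+9del	-	c.622+14del	-	c.1531C>T	p.R511W
FA24	ETFB	c.340_342del	p.Lys114del	c.253C>T	p.Arg85Ter	c.82G>A	p.Gly28Ser
FA25	ACADS	c.172C>T	p.R58*	c.286G>A	p.G96S	-	-
FA26	ACADS	c.220C>T	p.P74S	c.413del	p.N138Mfs*36	-	-
FA27	ACADS	c.1031A>G	p.E344G	-	-	-	-
FA28	ACADS	c.413delA	p.N138Mfs*36	c.758T>G	p.V253G	-	-
FA29	ACADS	c.1130C>T	p.P377L	c.578C>T	p.S193L	-	-
FA30	ACADS	c.795+1G>A	-	c.1031A>G	p.E344G	-	-
FA31	ACADS	c.578>T	p.S193L	c.1031A>G	p.E344G	-	-
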