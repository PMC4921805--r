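cluster	element	snps	n_snps	haplogroup	chrom	start	end	printed_span	min_tract	max_tract	donors	note
1	LTR-2	V351,V352,V353,V354,V355,V356	6	E-V257*	chrY	2866271	2866356	86	86	246	chrY:3966976-3968339	V355 shared SNP with donor
2	LTR-2	V354,V356	2	E-V12*	chrY	2866347	2866356	10	10	57	chrY:3966976-3968339;chrX:8419802-8421096;chr7:145393687-145395025
3	LTR-2	V363,V365.2,V366	3	homoplasic	chrY	2866480	2866496	17	3	14	chrY:8166477-8168142	V363 mutation or conversion
4	LTR-2	V364,V365.1,V367	3	B1	chrY	2866490	2866505	16	16	69	chr10:19239555-19240773
5	LTR-2	V372,V374,V375.2,V376	4	A3-M28	chrY	2866617	2866630	14	14	41	chrY:7489271-7490822;chrY:28328893-28330444;chrY:24854475-24856026;chrY:25632458-25634009	same donors as cluster 8
6	LTR-2	V387,V388	2	A1-M31	chrY	2866786	2866791	6	NA	NA	NA	several putative donors
7	LTR-2	V380,V381,V382,V383,V384	5	B2-P6	chrY	2866724	2866733	10	10	89	chrY:6533820-6535364
8	LTR-2	V389,V390	2	E-M33	chrY	2866871	2866880	10	10	74	chrY:7489271-7490822;chrY:28328893-28330444;chrY:24854475-24856026;chrY:25632458-25634009	same donors as cluster 5
9	LTR-2	V376,V377	2	E-V22*	chrY	2866630	2866640	11	11	54	chr6:8665762-8667845
10	LTR-2	V390,V391,V392,V393,V394	5	C-M217	chrY	2866880	2866931	52	24	450	chrY:3966976-3968339	V394 mutation or conversion
11	LTR-2	V391,V392,V393	3	O-M117	chrY	2866881	2866903	23	23	34	chrY:3966976-3968339;chrX:89776222-89776267
12	LTR-2	V370,V371	2	homoplasic	chrY	2866613	2866613	2	NA	NA	NA	not analysed (span < 3 bp)
13	LTR-2	V357,V358,V360,V361,V362	5	J-M67*	chrY	2866398	2866421	24	24	83	chrY:8166477-8168142
14	LTR-24	V448,V449,V450,V451,V452,V453,V454,V455	9	I-M170*	chrY	16709731	16709794	63	63	96	chrY:16708816-16710643	intra-LTR conversion
15	LTR-24	V458,V459	2	A3-M51	chrY	16710137	16710139	3	3	26	chrY:16700564-16702229	conversion between HERV-flanking LTRs
16	LTR-24	V465,V466	2	B2-M182	chrY	16710593	16710595	3	3	49	chrY:16700564-16702229	conversion between HERV-flanking LTRs
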