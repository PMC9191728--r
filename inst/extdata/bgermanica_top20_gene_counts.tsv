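# Worked example: the 20 B. germanica genes attracting the most
# SINE-related piRNA reads (published analysis of assembly PYGN01 with
# small-RNA libraries GSE87031); combined-column layout
# "total (F - x; R - y)".  Coordinates 1-based inclusive.
Contig.ID	Strand	Start	End	Gene.ID	Gene.full.name	Reads.count
PYGN01000005	R	832095	893324	C1TC	C-1-tetrahydrofolate synthase	3557 (F - 1798; R - 1759)
PYGN01000073	F	440373	516715	LAC_1	Lachesin	2978 (F - 1450; R - 1528)
PYGN01000033	F	355625	439785	Tdc-1_0	Tyrosine decarboxylase	2889 (F - 1547; R - 1342)
PYGN01000033	F	656364	694669	K11H3-3	Putative tricarboxylate transport protein	2717 (F - 1343; R - 1374)
PYGN01000022	F	2406772	2456620	lhx3	LIM/homeobox protein Lhx3	2716 (F - 1396; R - 1320)
PYGN01000072	R	549086	581815	Diap1	Death-associated inhibitor of apoptosis 1	2655 (F - 1375; R - 1280)
PYGN01000005	R	2480629	2498464	Or88	Odorant receptor 88	2488 (F - 1127; R - 1361)
PYGN01000049	R	1701575	1765331	Cher_2	Filamin-A	2478 (F - 1267; R - 1211)
PYGN01000083	R	266347	296944	Pex1	Peroxisome biogenesis factor 1	2469 (F - 1167; R - 1302)
PYGN01000050	R	461156	514648	Ir76b	Ionotropic receptor 76b	2433 (F - 1150; R - 1283)
PYGN01000086	R	1254016	1267262	SCD	Acyl-CoA desaturase	2416 (F - 1247; R - 1169)
PYGN01000005	F	3153139	3200419	IFT140	Intraflagellar transport protein 140	2414 (F - 1183; R - 1231)
PYGN01000060	F	519801	563025	APN1_0	Aminopeptidase N	2400 (F - 1127; R - 1273)
PYGN01000016	F	1455716	1479561	Ir41a12	Ionotropic receptor 41a12	2290 (F - 1109; R - 1181)
PYGN01000056	F	343658	370413	Rcbtb1	RCC1 domain-containing protein 1	2290 (F - 1181; R - 1109)
PYGN01000029	R	1139008	1166057	March6	E3 ubiquitin-protein ligase MARCH6	2104 (F - 1032; R - 1072)
PYGN01000024	R	2118061	2140175	CCND2	G1/S-specific cyclin-D2	2081 (F - 1089; R - 992)
PYGN01000005	F	1745668	1812688	Tle4_1	Transducin-like enhancer protein 4	2072 (F - 1020; R - 1052)
PYGN01000010	F	1604309	1616070	Smg9	Protein SMG9	2055 (F - 999; R - 1056)
PYGN01000038	F	2126408	2158714	HIRA	Protein HIRA	2047 (F - 1051; R - 996)
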