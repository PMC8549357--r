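panel	filter	applicable_fp	removed_fp	unique_fp	applicable_tp	removed_tp
SNP	any	1294894	821144	NA	23683336	6558764
SNP	dist_snp	1294893	509391	199322	23683334	3853196
SNP	qual	967140	260965	54816	18259439	2272104
SNP	direction_bias	94608	25258	5662	1624305	19366
SNP	vaf	1137831	288645	78160	20317662	286053
SNP	qd	711545	75558	11433	14435763	807924
SNP	strand_bias	691565	68990	17629	12123579	75565
SNP	alt_reads	978302	90049	836	18258302	132122
SNP	dist_indel	760877	60064	20150	15957723	67755
SNP	depth	1294828	94623	0	23683315	205065
INDEL	any	135295	114314	NA	157898	41150
INDEL	dist_indel	135277	86324	40709	157861	5632
INDEL	vaf	82042	31135	6961	118698	24410
INDEL	strand_bias	33977	8288	1632	46093	666
INDEL	depth	119480	23040	0	133409	2879
INDEL	dist_snp	135294	25567	3844	157898	10597
INDEL	qual	106597	12229	1834	133697	1530
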