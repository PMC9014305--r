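locus	category	circ_start	circ_end	predicted_length	aligned_wt	circ_wt	aligned_ko	circ_ko	total_circ_wt	total_circ_ko
sR01	cdbox	47786	47847	62	2167	395	1776	7	18	0
sR05	cdbox	116401	116466	66	445142	354	333035	0	54	0
sR13	cdbox	279797	279863	67	59144	47	58048	0	2	0
sR15	cdbox	316130	316191	62	1629229	698	1523609	8	113	0
sR20	cdbox	558818	558879	62	1622	21	1400	0	46	0
sR28	cdbox	832364	832425	62	65322	72	54801	1	123	0
sR29	cdbox	940146	940209	64	475600	36	283215	0	11	0
sR31	cdbox	963853	963919	67	562648	4655	721884	34	343	1
sR34	cdbox	1103565	1103626	62	20161	119	19347	0	14	0
sR37	cdbox	1159583	1159644	62	356961	44	195173	1	21	0
sR38	cdbox	1167276	1167338	63	11287	106	4940	0	3	0
sR41	cdbox	1226838	1226899	62	1967	31	610	0	202	0
sR42	cdbox	1226948	1227017	70	12085	7194	17658	10	145	0
sR46	cdbox	1371729	1371790	62	176232	188	79569	3	258	3
sR49	cdbox	1446209	1446268	60	62328	358	36039	1	376	0
sR52	cdbox	1476851	1476917	67	28701	467	42613	6	4	0
sR58	cdbox	1947796	1947856	61	926	95	845	0	5	0
sR61	cdbox	2070055	2070116	62	100212	92	31284	0	22	0
ncRNA01	ncRNA	1053772	1053834	63	1267983	68	587087	3	48	0
ncRNA02	ncRNA	1257020	1257081	62	8320	139	6342	0	135	0
ncRNA03	ncRNA	1593064	1593134	71	7565	403	9633	1	4	0
TK0058	protein_coding	51411	51477	67	1816	589	780	1	493	1
TK2034	protein_coding	1826865	1826930	66	771	66	477	2	22	0
TK2109	protein_coding	1894519	1894579	61	14240	28	11134	0	857	4
tRNA-Trp	tRNA_intron	1945728	1945789	62	28907	2023	23156	1292	1415	987
TK0135	protein_coding	108461	116468	8008	457060	90	576950	110	0	0
TK0894	protein_coding	779653	779796	144	317	28	215	28	0	0
TK1980	protein_coding	1784662	1785579	918	1322	42	739	53	0	0
16S RNA-c1	rRNA	2022801	2024382	1582	404505	96319	268720	53186	6836	4733
23S RNA-c1	rRNA	2024584	2027631	3048	867077	27733	610944	11628	282955	205719
23S RNA-c2	rRNA	2024595	2027605	3011	867051	83	610939	35	42016	23246
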