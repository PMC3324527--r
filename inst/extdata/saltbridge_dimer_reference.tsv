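pair	pos_residue	neg_residue	alloform	water	intra	intra_sem	inter	inter_sem	total	total_sem
R5-D1	5	1	Ab40	SPCE	11	3	2	1	13	3
R5-E3	5	3	Ab40	SPCE	18	4	3	2	21	4
R5-D7	5	7	Ab40	SPCE	14	3	1	1	15	3
R5-E11	5	11	Ab40	SPCE	8	2	1	1	9	2
R5-E22	5	22	Ab40	SPCE	7	3	3	2	10	3
R5-D23	5	23	Ab40	SPCE	4	2	4	2	8	2
K16-D1	16	1	Ab40	SPCE	3	1	7	2	10	2
K16-E3	16	3	Ab40	SPCE	2	1	6	2	8	2
K16-D7	16	7	Ab40	SPCE	4	2	1	1	5	2
K16-E11	16	11	Ab40	SPCE	4	1	1	1	5	1
K16-E22	16	22	Ab40	SPCE	1	1	1	1	2	1
K16-D23	16	23	Ab40	SPCE	1	1	3	1	4	2
K28-D1	28	1	Ab40	SPCE	3	1	5	2	7	2
K28-E3	28	3	Ab40	SPCE	1	1	3	1	4	2
K28-D7	28	7	Ab40	SPCE	3	1	2	1	6	2
K28-E11	28	11	Ab40	SPCE	2	1	0	0	2	1
K28-E22	28	22	Ab40	SPCE	9	2	0	0	9	2
K28-D23	28	23	Ab40	SPCE	15	3	2	1	17	3
R5-D1	5	1	Ab40	TIP3P	9	3	1	1	10	3
R5-E3	5	3	Ab40	TIP3P	32	5	0	0	32	5
R5-D7	5	7	Ab40	TIP3P	12	3	0	0	12	3
R5-E11	5	11	Ab40	TIP3P	6	2	5	2	11	3
R5-E22	5	22	Ab40	TIP3P	8	3	5	2	13	4
R5-D23	5	23	Ab40	TIP3P	3	2	2	2	5	2
K16-D1	16	1	Ab40	TIP3P	7	2	2	1	9	3
K16-E3	16	3	Ab40	TIP3P	4	2	2	1	6	2
K16-D7	16	7	Ab40	TIP3P	4	2	0	0	4	2
K16-E11	16	11	Ab40	TIP3P	9	2	0	0	9	2
K16-E22	16	22	Ab40	TIP3P	3	2	2	1	5	2
K16-D23	16	23	Ab40	TIP3P	2	1	1	1	4	2
K28-D1	28	1	Ab40	TIP3P	4	1	3	2	7	2
K28-E3	28	3	Ab40	TIP3P	3	1	5	2	8	2
K28-D7	28	7	Ab40	TIP3P	4	2	0	0	5	2
K28-E11	28	11	Ab40	TIP3P	2	1	1	1	4	1
K28-E22	28	22	Ab40	TIP3P	11	3	5	2	15	3
K28-D23	28	23	Ab40	TIP3P	17	3	3	1	20	4
R5-D1	5	1	Ab42	SPCE	27	5	3	2	30	5
R5-E3	5	3	Ab42	SPCE	27	4	2	1	28	4
R5-D7	5	7	Ab42	SPCE	13	3	1	1	14	3
R5-E11	5	11	Ab42	SPCE	3	2	2	2	6	2
R5-E22	5	22	Ab42	SPCE	6	2	2	1	8	3
R5-D23	5	23	Ab42	SPCE	1	1	2	1	3	1
K16-D1	16	1	Ab42	SPCE	1	0	1	1	1	1
K16-E3	16	3	Ab42	SPCE	2	1	1	1	4	2
K16-D7	16	7	Ab42	SPCE	3	2	3	1	6	2
K16-E11	16	11	Ab42	SPCE	5	2	2	1	7	2
K16-E22	16	22	Ab42	SPCE	1	1	0	0	1	1
K16-D23	16	23	Ab42	SPCE	1	1	3	2	5	2
K28-D1	28	1	Ab42	SPCE	4	1	1	1	5	1
K28-E3	28	3	Ab42	SPCE	1	0	1	1	2	1
K28-D7	28	7	Ab42	SPCE	2	1	1	1	4	2
K28-E11	28	11	Ab42	SPCE	2	1	3	2	5	2
K28-E22	28	22	Ab42	SPCE	4	1	0	0	4	1
K28-D23	28	23	Ab42	SPCE	5	2	1	1	6	2
R5-D1	5	1	Ab42	TIP3P	26	4	0	0	27	4
R5-E3	5	3	Ab42	TIP3P	36	4	1	1	36	4
R5-D7	5	7	Ab42	TIP3P	16	3	0	0	16	3
R5-E11	5	11	Ab42	TIP3P	6	2	1	1	8	3
R5-E22	5	22	Ab42	TIP3P	5	2	5	2	10	3
R5-D23	5	23	Ab42	TIP3P	1	1	3	2	4	2
K16-D1	16	1	Ab42	TIP3P	2	1	2	1	4	1
K16-E3	16	3	Ab42	TIP3P	4	2	3	1	6	2
K16-D7	16	7	Ab42	TIP3P	1	1	1	1	2	1
K16-E11	16	11	Ab42	TIP3P	4	2	4	2	9	3
K16-E22	16	22	Ab42	TIP3P	2	1	2	1	4	2
K16-D23	16	23	Ab42	TIP3P	1	1	3	2	4	2
K28-D1	28	1	Ab42	TIP3P	5	2	1	1	6	2
K28-E3	28	3	Ab42	TIP3P	2	1	0	0	2	1
K28-D7	28	7	Ab42	TIP3P	2	1	3	1	4	2
K28-E11	28	11	Ab42	TIP3P	2	1	3	2	5	2
K28-E22	28	22	Ab42	TIP3P	8	2	4	2	13	3
K28-D23	28	23	Ab42	TIP3P	9	3	3	1	13	3
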