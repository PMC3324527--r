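pair	pos_residue	neg_residue	alloform	water	intra	intra_sem
R5-D1	5	1	Ab40	SPCE	8	4
R5-E3	5	3	Ab40	SPCE	17	5
R5-D7	5	7	Ab40	SPCE	19	5
R5-E11	5	11	Ab40	SPCE	11	4
R5-E22	5	22	Ab40	SPCE	8	4
R5-D23	5	23	Ab40	SPCE	2	2
K16-D1	16	1	Ab40	SPCE	1	0
K16-E3	16	3	Ab40	SPCE	2	2
K16-D7	16	7	Ab40	SPCE	3	2
K16-E11	16	11	Ab40	SPCE	7	3
K16-E22	16	22	Ab40	SPCE	3	2
K16-D23	16	23	Ab40	SPCE	5	3
K28-D1	28	1	Ab40	SPCE	10	4
K28-E3	28	3	Ab40	SPCE	6	2
K28-D7	28	7	Ab40	SPCE	0	0
K28-E11	28	11	Ab40	SPCE	1	0
K28-E22	28	22	Ab40	SPCE	12	4
K28-D23	28	23	Ab40	SPCE	9	3
R5-D1	5	1	Ab40	TIP3P	27	6
R5-E3	5	3	Ab40	TIP3P	24	6
R5-D7	5	7	Ab40	TIP3P	11	4
R5-E11	5	11	Ab40	TIP3P	18	5
R5-E22	5	22	Ab40	TIP3P	12	4
R5-D23	5	23	Ab40	TIP3P	4	2
K16-D1	16	1	Ab40	TIP3P	3	2
K16-E3	16	3	Ab40	TIP3P	2	2
K16-D7	16	7	Ab40	TIP3P	3	2
K16-E11	16	11	Ab40	TIP3P	7	3
K16-E22	16	22	Ab40	TIP3P	6	3
K16-D23	16	23	Ab40	TIP3P	2	2
K28-D1	28	1	Ab40	TIP3P	9	3
K28-E3	28	3	Ab40	TIP3P	3	1
K28-D7	28	7	Ab40	TIP3P	3	2
K28-E11	28	11	Ab40	TIP3P	5	3
K28-E22	28	22	Ab40	TIP3P	12	4
K28-D23	28	23	Ab40	TIP3P	14	4
R5-D1	5	1	Ab42	SPCE	36	6
R5-E3	5	3	Ab42	SPCE	28	5
R5-D7	5	7	Ab42	SPCE	4	3
R5-E11	5	11	Ab42	SPCE	3	2
R5-E22	5	22	Ab42	SPCE	7	4
R5-D23	5	23	Ab42	SPCE	7	4
K16-D1	16	1	Ab42	SPCE	5	2
K16-E3	16	3	Ab42	SPCE	2	2
K16-D7	16	7	Ab42	SPCE	3	2
K16-E11	16	11	Ab42	SPCE	9	4
K16-E22	16	22	Ab42	SPCE	3	2
K16-D23	16	23	Ab42	SPCE	4	2
K28-D1	28	1	Ab42	SPCE	0	0
K28-E3	28	3	Ab42	SPCE	3	2
K28-D7	28	7	Ab42	SPCE	4	3
K28-E11	28	11	Ab42	SPCE	5	3
K28-E22	28	22	Ab42	SPCE	10	4
K28-D23	28	23	Ab42	SPCE	8	4
R5-D1	5	1	Ab42	TIP3P	37	7
R5-E3	5	3	Ab42	TIP3P	32	6
R5-D7	5	7	Ab42	TIP3P	6	3
R5-E11	5	11	Ab42	TIP3P	14	5
R5-E22	5	22	Ab42	TIP3P	12	5
R5-D23	5	23	Ab42	TIP3P	2	2
K16-D1	16	1	Ab42	TIP3P	2	2
K16-E3	16	3	Ab42	TIP3P	5	3
K16-D7	16	7	Ab42	TIP3P	10	4
K16-E11	16	11	Ab42	TIP3P	8	3
K16-E22	16	22	Ab42	TIP3P	4	3
K16-D23	16	23	Ab42	TIP3P	5	3
K28-D1	28	1	Ab42	TIP3P	6	3
K28-E3	28	3	Ab42	TIP3P	9	4
K28-D7	28	7	Ab42	TIP3P	2	1
K28-E11	28	11	Ab42	TIP3P	6	3
K28-E22	28	22	Ab42	TIP3P	15	4
K28-D23	28	23	Ab42	TIP3P	14	4
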