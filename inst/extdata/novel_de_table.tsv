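mirna_id	sequence	F0_std	F3_std	R0_std	R3_std	fc_f	sig_f	fc_r	sig_r
novel_mir_107	AGGGATGGTATGCACTGAAGC	0.01	3.71	0.01	4.55	8.54	**	8.83	**
novel_mir_117	AAGAGGAAGAGAGAGAGGGTG	0.01	0.01	0.01	12.33	NA		10.27	**
novel_mir_134	GAGGCAAGGAGGTGGAATAGAC	0.01	3.90	NA	NA	8.61	**	NA
novel_mir_136	AAGCAAGTTGGGGTAGGCTAA	0.01	1.30	NA	NA	7.02	**	NA
novel_mir_142	TGAAACGGTACGGCTGATAAGTT	0.01	1.06	NA	NA	6.73	**	NA
novel_mir_21	TAAATATATAACATCAGGACC	1.10	0.01	NA	NA	-6.79	**	NA
novel_mir_34	CGTACCACCGTCCGGGACTAA	1.14	0.01	NA	NA	-6.84	**	NA
novel_mir_37	TCCAATGCATACCGTCCCTAA	3.94	0.01	5.03	0.01	-8.62	**	-8.97	**
novel_mir_41	CCGAGAGGTAGGGCCGGTCGAA	6.55	0.01	12.83	10.34	-9.35	**	NA
novel_mir_54	TCCAAATTATAAGACGTTTTG	1.03	0.34	1.57	0.79	-1.60	**	-1.00	*
novel_mir_57	GGGCTGGTTCGGCTGGTGGAA	1.10	0.01	NA	NA	-6.79	**	NA
novel_mir_68	ATAAGACGTTTTGGCTTTTCT	3.90	0.01	NA	NA	-8.61	**	NA
novel_mir_72	AAGAGGAAGAGAGAGAGGGTGA	16.09	0.01	16.17	0.01	-10.65	**	-10.66	**
novel_mir_74	TCTTGGATTTGCATTGGATGCC	1.18	0.01	NA	NA	-6.89	**	NA
novel_mir_79	CGGCCGACGCGCCGCGGCGGGC	2.64	0.01	2.19	0.01	-8.05	**	-7.77	**
novel_mir_80	TGGTTGTTGGCTGGCCATGGCTG	5.44	5.93	6.57	0.01	NA		-9.36	**
novel_mir_81	GCTAGAGGCAGCAACTGCATA	9.94	0.01	NA	NA	-9.96	**	NA
novel_mir_89	CAATCGTGGACCAACTAGGCT	4.85	0.01	3.53	4.01	-8.92	**	0.18
novel_mir_91	CCTGCGTCGCACGGATTCGT	1114.45	3231.35	NA	NA	1.54	**	NA
novel_mir_97	GTCGTCGCCGTCGTCGTCGTC	1.10	0.34	1.19	0.79	-1.71	**	-0.60
novel_mir_1	GGAATGTTGTCTGGTCGGAGA	9.31	7.37	10.48	0.01	-0.34		-10.03	**
novel_mir_130	GGCATGGGAACATGTAGGAAGG	NA	NA	0.01	2.81	NA		8.14	**
novel_mir_171	TTTGAATAAGACGAGTGGTCA	NA	NA	10.33	0.01	NA		-10.01	**
novel_mir_183	TAAGCTGGCTGATGCTGTTTT	NA	NA	1.65	0.01	NA		-7.37	**
novel_mir_216	TCGAGGCCGAACGGATAAGTC	NA	NA	0.01	1.53	NA		7.26	**
novel_mir_228	TTTTTGGTGATTGATGACAAC	NA	NA	0.01	2.90	NA		8.18	**
novel_mir_28	AGGTCATGCTGTAGTTTCATC	NA	NA	1.30	3.02	NA		1.21	**
novel_mir_3	GGCTGAGCATGCCGCCGTCGAG	0.75	1.49	7.18	2.40	1.00		-1.58	**
novel_mir_58	CGTCGCCGTCGTCGTCGTCGTC	2.29	1.64	1.11	0.50	-0.48		-1.16	*
novel_mir_64	AGGGGTTGTGCGGCGGTGCCC	NA	NA	1.42	0.01	NA		-7.15	**
novel_mir_67	AAAAACTTTGTACTAAAGCATA	NA	NA	2.27	0.01	NA		-7.82	**
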