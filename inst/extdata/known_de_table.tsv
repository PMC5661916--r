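mirna_id	sequence	F0_std	F3_std	R0_std	R3_std	fc_f	sig_f	fc_r	sig_r
miR1310	GAGGCATCGGGGGCGCAACGCC	8.32	29.24	15.78	30.98	1.81	**	0.97
miR1520d	ATCAGAACTGGTACGGACAA	574.08	1917.98	1131.16	2620.83	-1.74	**	1.21
miR157a	TTGACAGAAGATAGAGAGCAC	4.65	9.68	4.34	4.26	1.06	**	-0.02
miR2199	TGATAACTTGACGGATCGC	59.42	179.46	129.61	272.82	1.59	**	1.07	**
miR2916	GGGGCTCGAAGACGATCAGAT	46.30	198.06	128.65	255.78	-2.10	**	0.99
miR5054	TCCCCACGGACGGCGCCA	50.00	117.65	81.84	164.77	1.23	**	1.00	**
miR5059	CGTTCCTGGGCAGCAACACCA	35.92	97.80	84.02	201.88	1.44	**	1.26	**
miR5072	GTTCCCCAGCGGAGTCGCCA	2.16	7.70	5.34	20.97	1.82	**	1.97	**
miR5077	TTCACGTCGGGTTCACCA	104.90	321.31	104.90	321.30	1.62	**	1.62	**
miR5152-3p	AGTCCTGCTATACCCACCA	0.59	2.02	1.30	3.76	1.77	**	1.52	**
miR5575	TGGATTTTGGAATGTTTTGGT	0.39	1.98	3.03	2.23	2.32	**	-0.44
miR5671	CATGGTGGTGACGGGTGAC	32.73	70.96	72.74	126.88	1.12	**	0.80
miR5813	ACAGCAGGACGGTGGTCATGGA	63.41	206.30	132.57	269.48	1.70	**	1.02	**
miR6196	GGGACGAGAAAGATGGGAGGA	5.12	11.12	17.93	21.15	1.12		1.09	**
miR6300	GTCGTTGTAGTATAGTGGTG	101.38	217.53	216.10	284.36	1.10	**	0.40
miR6478	CCGACCTTAGCTCAGTTGGTA	14.70	32.52	30.53	51.46	1.14	**	0.75
miR8155	CGTAACCTGGCTCCGATACCA	4.14	9.20	8.10	16.96	1.15	**	1.06	**
miR894	GTTTCACGTCGGGTTCACCA	334.04	1108.12	1040.41	2131.64	1.72	**	1.03
miR160a	TGCCTGGCTCCCTGTATGCCA	13.92	4.43	4.64	8.89	-1.65	**	0.94
miR169b	CAGCCAAGGATGACTTGCCGG	43.54	20.76	38.28	39.38	-1.06	**	0.04
miR169e-3p	GGCAGTCTCCTTGGCTAGC	73.19	31.02	14.24	21.84	-1.24	**	0.62
miR397-5p	TTGACTGCAGCGTTGATGAGC	9.82	12.34	2.30	3.64	1.12	**	0.66
miR528-5p	TGGAAGGGGCATGCAGAGGAG	123.62	49.19	303.86	262.15	-1.32	**	-0.21
miR5532	ATGGAAATTGATGACAAAGGGG	1.58	0.77	1.46	1.20	-1.03	*	-0.28
miR1861d	TGCGTCATCAGGCAGGAACTGG	NA	NA	3.30	15.34	NA		2.22	**
miR395o-3p	TGAAGTGTTTGGGTGAACTC	2.60	1.64	0.88	2.56	-0.66		1.54	**
miR5221	AACGAGATGGTGTTTTACTT	NA	NA	3.00	14.23	NA		2.24	**
miR5242	TATTTAGAACAGGCGATGTCA	1.26	1.49	3.68	13.24	0.24		1.84	**
miR5272f	GAATTGATTTGTGTTGGATAAATT	3.27	2.64	0.80	1.78	-0.30		1.14	**
miR394a	TTGGCATTCTGTCCACCTCC	4.26	7.78	0.88	0.74	1.03	**	-0.96
miR863-5p	TTATAGTCTTGTGGATCAAAT	NA	NA	0.23	1.53	NA		2.73	**
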