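tier	name	length_nt	sequence	chromosome	start	end	location	mean_control_tpm	mean_mutant_tpm	log2fc
high	novel-miR01	21	AATTACCTATCATTCGTGGGT	Chromosome 5	2873872	2874135	Intergenic	3.5	0.15	-4.523
high	novel-miR02	21	TGGGTCACCTGCGCCTGCGTT	Chromosome 14	2122168	2122460	Intergenic	1.37	0.08	-4.169
high	novel-miR03	23	TGAATGTAAACTCCCCCTCCCCA	Chromosome 11	2785306	2785459	Intron	1.18	0.08	-3.956
high	novel-miR04	23	CAGCGGTGGGCTGAGGGTAGACG	Chromosome 12	8503745	8503841	Intron	375.57	32.48	-3.531
high	novel-miR05	20	TATGCTGAGCACCCCGGTCG	Chromosome 10	3368596	3368743	Intergenic	3.11	0.32	-3.289
high	novel-miR06	23	TACGCATCCTAAGTCGAGTCGTG	Chromosome 12	9061162	9061249	Intron	55.04	6.52	-3.078
high	cre-miR1166.1	21	TGGACCTCGCGGCCCTGGAGG	Chromosome 5	577911	578282	Intergenic	14.93	1.83	-3.028
high	novel-miR07	20	TGCGGTCGGCGTGTGTGTGG	Chromosome 10	1120701	1121049	Intron	2.62	0.67	-1.976
high	novel-miR08	21	AACAGGTTATGAGCCCCGGAC	Chromosome 7	2371050	2371155	Intron	3.22	0.85	-1.92
high	novel-miR09	21	ACGCCGATGAACTCTGCAATG	Chromosome 13	2605312	2605488	Intergenic	4.13	1.24	-1.737
high	novel-miR10	20	CCCGTTCCACTGGGACATCC	Chromosome 12	6266530	6266662	Intron	61.72	19.9	-1.633
high	novel-miR11	20	TAGGATCCTAATGAATGTGA	Chromosome 1	7867220	7867479	Intron	5.14	1.98	-1.376
high	novel-miR12	23	ACCGGTCGAGAGAGTGTTGTCGG	Chromosome 15	299894	300127	Intron	31.24	12.49	-1.322
high	novel-miR13	21	TAGCCAACAAGGCCGCCGAAG	Chromosome 15	703183	703279	Intron	9.78	4.3	-1.184
medium	cre-miR1165-5p	21	TACCGTACAAGCGGTCCGTCC	Chromosome 3	1999966	2000090	Intron	2745.53	1478.23	-0.893
medium	novel-miR14	22	TTAGGCCCCGTGCTGGCGAATG	Chromosome 17	1131227	1131348	Intron	11.19	6.12	-0.87
medium	cre-miR1165-3p	22	ACGGACCGCTTGTACGGATATG	Chromosome 3	1999966	2000090	Intron	3202.79	1831.38	-0.806
medium	novel-miR15	21	AGGCCTATTACCGCGTCGAAG	Chromosome 7	2713511	2713622	Intron	19.31	11.05	-0.806
medium	cre-miR918	21	TACCTGAAGCGGACATCTTGC	Chromosome 5	1014118	1014386	Intergenic	221.83	130.13	-0.769
medium	cre-miR910	21	AGCAGCGTCGGGCTCGACCGC	Chromosome 14	966108	966334	Intergenic	40883.05	24703.94	-0.727
medium	novel-miR16	21	TAGCCGATGGAACCCCCAGCT	Chromosome 5	910438	910438	Intron	16175.43	9927.71	-0.704
medium	miR_t20*	21	TAGAGCTCGAAGAACTTGGGA	Chromosome 6	6776096	6776203	Intergenic	98402.4	62535.6	-0.654
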