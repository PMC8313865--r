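locus_id	chrom	start	end	unit	ref_repeat_count	flank_left	flank_right
L00001	chrX	0	22	AC	11	CCTCTATTGTACTCCTATCTCAGCGCCTAT	CTTTGCGTGACTCGCGGAGTCTAGTCGATC
L00002	chrX	0	32	AC	16	GCCACTTCGACTGCGCGGTTAGGAGCAATA	TCAGGCACACAAATAAAACTGTGGCCTCTT
L00003	chrX	0	32	AC	16	AGATGTGCGTGGGCGCATGGGAGGCGCTGG	CCCGCGGCCTGTATAGGTAGCTTACGCTTC
L00004	chrX	0	30	AC	15	CCATATTGTATGGAGGTAATCGTAAGGTCG	ACCAGACCCTTCCCTCTCTGATCCCAGCTA
L00005	chrX	0	26	AC	13	CGGTTGGAGGTCCGCCACACAACTACTCTT	AGATTGCCACAGGACCGAGCACCTATATGG
L00006	chrX	0	40	AC	20	TTAAACGGCTAGACGAGTACGGACAGACCA	GCACGTCATCAGAGTAATCCAAGACCTGCG
L_A7	chrX	0	7	A	7	CCTCTATTGTACTCCTATCTCAGCGCCTAT	CTTTGCGTGACTCGCGGAGTCTAGTCGATC
L_AC10	chrX	0	20	AC	10	GCCACTTCGACTGCGCGGTTAGGAGCAATA	TCAGGCACACAAATAAAACTGTGGCCTCTT
L_AG12	chrX	0	24	AG	12	AGATGTGCGTGGGCGCATGGGAGGCGCTGG	CCCGCGGCCTGTATAGGTAGCTTACGCTTC
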