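family	member	species	seq	length	mir_length	mn	mean_count
miR156	a	ath	tgacagaagagagtgagcac	20	21	0	2247.09
miR156	g	ath	ggacagaagagagtgagcac	20	20	0	13.01
miR156	h	vvi	ttgacagaagagagagagcat	21	20	1	5.73
miR156	i	ath	tgacagaagagagagagca	19	21	0	1.92
miR156	j	ath	tgacagaagagagagagcac	20	21	0	4.43
miR159	a	ath	tttggattgaagggagct	18	21	0	1.28
miR160	a	ath	tgcctggctccctgtatgcca	21	21	0	3125.22
miR166	a	ath	tcggaccaggcttcattcccc	21	21	0	309522.05
miR171	i-5p	osa	aggtattggcgcgcctcaatt	21	21	1	0.97
miR319	a	ath	cttggactgaagggagctcccttt	24	21	0	8.34
miR390	a	ath	aagctcaggagggatagcg	19	21	0	235.63
miR395	d	bdi	tccaagtgtttcgggtactctagg	24	21	2	1.77
miR396	b	ath	ttccacagctttcttgaactt	21	21	0	13.79
miR408		ath	atgcactgcctcttccctggc	21	21	0	388.61
miR535	-5p	osa	tgacaacgagagagagcacgc	21	21	0	4374.19
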