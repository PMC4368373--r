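name	member	pen_seq	cre_seq	mn
pen-miR8183	.2	gggactggaaggaggctgaga	acctggaaggaggctgag	2
pen-miR8185		taaagatgatgggttttgttg	aatgatgatgggttttgt	1
pen-miR1144	b	gtagggtggaggcaggca	tgggtagtgtggcggcaggcag	2
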