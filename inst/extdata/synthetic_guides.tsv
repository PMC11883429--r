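name	protospacer	pam
sg1	CCGTTTCTAGCATTAGTCCG	GGG
sg2	ACCGCCGCTGTTTAAGGGTT	CGG
sg3	AGGAATCCTCTTGCATGTAC	AGG
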