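chrom	start	end	gene
3	1134260	1445901	CNTN6
16	82660399	83830204	CDH13
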