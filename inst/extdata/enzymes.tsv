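name	site	cut_offset	fill_in
MboI	GATC	0	TRUE
DpnII	GATC	0	TRUE
AluI	AGCT	2	TRUE
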