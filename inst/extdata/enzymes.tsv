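name	recognition	cut_offset_top	cut_offset_bottom	check_only
SapI	GCTCTTC	1	4	FALSE
LguI	GCTCTTC	1	4	FALSE
BsaI	GGTCTC	1	5	FALSE
DpnI	GATC	0	0	TRUE
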