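chromosome	class	type2_n	type2_exclusive	type1_n	type1_exclusive	total
LS1	DEL	29	29	3	3	32
LS1	INS	34	34	0	0	34
LS1	SNP	79	75	13	9	88
LS2	DEL	25	21	7	3	27
LS2	INS	18	17	1	0	18
LS2	SNP	54	54	1	1	55
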