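molecule	a_pct	c_pct	g_pct	t_pct	gc_pct	length
M1	27.90	22.18	22.22	27.70	44.40	169406
M2	27.60	21.63	23.26	27.52	44.90	56355
M3	27.46	22.25	22.73	27.55	45.00	97120
M4	27.70	22.58	22.44	27.29	45.00	113687
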