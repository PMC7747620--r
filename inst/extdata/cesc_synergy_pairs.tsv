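mirna_a	mirna_b	pair_p	pair_hr	hr_a	hr_b
miR-335-5p	miR-4677-5p	4.33e-05	3.09	1.75	1.84
miR-335-5p	miR-7641	1.45e-04	2.82	1.75	1.82
miR-216b-5p	miR-585-5p	6.58e-05	2.95	1.92	1.65
miR-130b-3p	miR-335-5p	3.13e-04	2.64	1.66	1.75
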