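station	depth_category	treatment	replicate	time_h	ch4_nmol_headspace	atom_pct_13c
S5	surface	MPn	A	0	4.4326	1.07958
S5	surface	MPn	A	6	4.0576	1.59091
S5	surface	MPn	A	12	3.7158	1.95327
S5	surface	MPn	A	24	3.4222	3.06653
S5	surface	MPn	A	48	3.1906	5.25815
S5	surface	MPn	B	0	4.4326	1.19958
S5	surface	MPn	B	6	4.0643	1.75949
S5	surface	MPn	B	12	3.7287	2.34465
S5	surface	MPn	B	24	3.4474	3.84619
S5	surface	MPn	B	48	3.2404	6.65635
S5	surface	DIC	A	0	4.4326	1.14777
S5	surface	DIC	A	6	4.0397	1.03589
S5	surface	DIC	A	12	3.6815	1.24318
S5	surface	DIC	A	24	3.3552	0.95063
S5	surface	DIC	A	48	3.0577	1.07821
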