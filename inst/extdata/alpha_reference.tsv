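marker	species	alpha_min	alpha_opt	alpha_max	replicate_correlation
Hi08h08	Apple	0.45	0.57	0.69	0.98
Hi09F01	Apple	0.69	0.80	0.90	0.98
Hi15h12	Apple	0.34	0.43	0.52	0.98
Hi22d06	Apple	0.57	0.74	0.90	1.00
Mdo.chr1.18	Apple	0.60	0.61	0.61	0.98
NZmsCN943067	Apple	0.57	0.66	0.74	0.99
NZmsEB116209	Apple	0.55	0.70	0.84	0.99
NZmsEB146613	Apple	0.58	0.73	0.87	1.00
SAmsCN944528	Apple	0.64	0.78	0.91	0.99
SAmsEB132187	Apple	0.76	0.82	0.88	1.00
TsuGNH124	Pear	0.52	0.60	0.67	0.97
TsuGNH161	Pear	0.53	0.73	0.93	1.00
TsuGNH179	Pear	0.89	0.93	0.97	0.99
TsuGNH194	Pear	0.53	0.75	0.96	1.00
TsuGNH204	Pear	0.43	0.62	0.80	0.99
TsuGNH207	Pear	0.53	0.75	0.97	1.00
TsuGNH208	Pear	0.87	0.89	0.91	0.99
TsuGNH250	Pear	0.53	0.75	0.97	1.00
CsFM1097	Tea	0.55	0.71	0.87	0.99
CsFM1206	Tea	0.63	0.77	0.90	1.00
CsFM1566	Tea	0.71	0.83	0.95	0.99
MSE0348	Tea	0.73	0.85	0.97	0.99
TM107	Tea	0.72	0.85	0.98	0.98
TM348	Tea	0.61	0.77	0.93	0.99
TM485	Tea	0.72	0.84	0.96	1.00
TM553	Tea	0.87	0.92	0.97	1.00
TM626	Tea	0.73	0.85	0.97	1.00
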