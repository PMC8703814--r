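marker	species	n_alleles	ho	he	pic	gbs_suitable
CH01b09b	Apple	3	0.59	0.67	0.52	FALSE
Hi08h08	Apple	3	0.56	0.54	0.47	TRUE
Hi09F01	Apple	4	0.79	0.63	0.57	TRUE
Hi15h12	Apple	3	0.26	0.29	0.26	TRUE
Hi22d06	Apple	5	0.79	0.74	0.69	TRUE
Mdo.chr1.18	Apple	5	0.63	0.64	0.57	TRUE
NZmsCN943067	Apple	5	0.61	0.51	0.46	TRUE
NZmsEB116209	Apple	3	0.70	0.66	0.58	TRUE
NZmsEB119405	Apple	4	0.52	0.61	0.48	FALSE
NZmsEB146613	Apple	3	0.74	0.63	0.56	TRUE
SAmsCN944528	Apple	5	0.65	0.61	0.55	TRUE
SAmsEB132187	Apple	3	0.65	0.60	0.52	TRUE
TsuGNH124	Pear	2	0.55	0.49	0.37	TRUE
TsuGNH161	Pear	3	0.62	0.60	0.52	TRUE
TsuGNH164	Pear	3	0.57	0.41	0.49	FALSE
TsuGNH179	Pear	3	0.83	0.59	0.52	TRUE
TsuGNH184	Pear	2	0.50	0.48	0.37	FALSE
TsuGNH194	Pear	2	0.35	0.37	0.30	TRUE
TsuGNH204	Pear	2	0.03	0.03	0.03	TRUE
TsuGNH207	Pear	2	0.28	0.24	0.21	TRUE
TsuGNH208	Pear	3	0.45	0.52	0.46	TRUE
TsuGNH250	Pear	2	0.41	0.33	0.27	TRUE
CsFM1097	Tea	4	0.43	0.49	0.45	TRUE
CsFM1206	Tea	3	0.50	0.57	0.50	TRUE
CsFM1566	Tea	4	0.61	0.49	0.45	TRUE
CsFM1595	Tea	5	0.62	0.63	0.57	FALSE
MSE0348	Tea	5	0.71	0.61	0.56	TRUE
MSE0354	Tea	4	0.64	0.80	0.57	FALSE
TM043	Tea	5	0.45	0.46	0.40	FALSE
TM107	Tea	6	0.80	0.69	0.64	TRUE
TM336	Tea	3	0.35	0.30	0.31	FALSE
TM348	Tea	5	0.64	0.59	0.51	TRUE
TM350	Tea	4	0.36	0.36	0.33	FALSE
TM464	Tea	7	0.51	0.57	0.45	FALSE
TM485	Tea	3	0.39	0.35	0.30	TRUE
TM553	Tea	3	0.80	0.50	0.39	TRUE
TM626	Tea	4	0.55	0.46	0.41	TRUE
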