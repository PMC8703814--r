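marker	species	avg_depth	avg_depth_replicate	ce_size_diff	result	affected_varieties
CH01b09b	Apple	6834	5724	1	stutter_errors	Jonathan;Sensyu
Hi08h08	Apple	342	470	1	comparable	
Hi09F01	Apple	395	605	-4	comparable	
Hi15h12	Apple	5329	4331	0	comparable	
Hi22d06	Apple	3611	4070	3	comparable	
Mdo.chr1.18	Apple	1206	1108	-2	comparable	
NZmsCN943067	Apple	1777	994	-3	comparable	
NZmsEB116209	Apple	747	534	3	comparable	
NZmsEB119405	Apple	2442	2481	1	allele_dropout	JM1;JM2;JM5;JM8
NZmsEB146613	Apple	8023	4636	1	comparable	
SAmsCN944528	Apple	6249	4003	-1	comparable	
SAmsEB132187	Apple	6621	4034	-3	comparable	
TsuGNH124	Pear	75	760	-2	comparable	
TsuGNH161	Pear	16758	23807	2	comparable	
TsuGNH164	Pear	716	1682	-3	low_depth_variety	Oushuu
TsuGNH179	Pear	1671	4622	-3	comparable	
TsuGNH184	Pear	21	116	-1	low_depth	
TsuGNH194	Pear	25406	12843	1	comparable	
TsuGNH204	Pear	3877	1957	-2	comparable	
TsuGNH207	Pear	2718	1231	2	comparable	
TsuGNH208	Pear	7348	3735	-1	comparable	
TsuGNH250	Pear	5021	2847	-2	comparable	
CsFM1097	Tea	1217	1868	-4	comparable	
CsFM1206	Tea	1259	1396	-2	comparable	
CsFM1566	Tea	857	1174	-1	comparable	
CsFM1595	Tea	195	268	0	low_depth_variety	Cha Chukanbohon No. 6
MSE0348	Tea	3580	2559	0	comparable	
MSE0354	Tea	10510	8783	1	allele_dropout	
TM043	Tea	3469	2528	0	allele_dropout	
TM107	Tea	2249	1645	-3	comparable	
TM336	Tea	14	12	1	low_depth	
TM348	Tea	691	577	-2	comparable	
TM350	Tea	514	357	-3	allele_dropout	
TM464	Tea	546	371	0	allele_dropout	
TM485	Tea	2365	2947	-2	comparable	
TM553	Tea	6800	8285	0	comparable	
TM626	Tea	1605	2288	0	comparable	
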