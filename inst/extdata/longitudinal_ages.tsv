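ind_id	sex	age_first	age_last	interval_printed
10	F	6.46	7.93	1.47
11	F	8.95	10.48	1.53
12	F	10.78	12.24	1.46
13	M	17.64	19.19	1.55
14	F	20.22	21.75	1.53
15	F	30.34	31.78	4.46
19	M	0.25	3.64	3.39
20	F	7.90	13.04	5.14
21	M	6.59	12.00	5.41
22	F	6.46	12.96	6.50
23	F	10.20	15.79	5.59
24	F	16.39	19.27	2.78
25	F	28.25	41.67	13.42
26	F	29.06	42.48	13.22
27	F	31.75	43.90	12.15
28	F	38.35	52.95	14.60
29	F	32.47	46.38	13.91
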