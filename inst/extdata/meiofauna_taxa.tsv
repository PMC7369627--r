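organism	control_avg	control_se	low_avg	low_se	medium_avg	medium_se	high_avg	high_se
Cladocera	33	6	27	2	90	42	57	16
Copepoda	16	5	17	3	16	4	21	8
Halacaridae	0	0	4	2	3	3	4	2
Kinorhyncha	0	0	0	0	40	15	146	31
Nematoda	78	18	142	35	662	196	1793	229
Ostracoda	0	0	0	0	16	13	9	2
Total	128	26	191	38	827	249	2030	232
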