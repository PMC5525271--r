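srna_id	transcript_id	site	score	site_reads	category	p_value
s01	t01	101	0	10	0	0.01
s02	t02	102	1.5	5	1	0.04
s03	t03	103	2	20	2	0.05
s04	t04	104	3	50	3	0.01
s05	t05	105	0	9	4	0.01
s06	t06	106	1.5	9	0	0.06
s07	t07	107	2	4	0	0.01
s08	t08	108	3	3	1	0.2
s09	t09	109	0	5	2	0.03
s10	t10	110	1.5	100	0	0.049
s11	t11	111	2	10	2	0.051
s12	t12	112	3	4	1	0.05
s13	t13	113	0	10	0	1
s14	t14	114	1.5	5	3	0.04
s15	t15	115	2	6	2	0.02
s16	t16	116	3	5	0	0.0099
s17	t17	117	0	1000	1	0.01
s18	t18	118	1.5	1	4	0.5
s19	t19	119	2	4	2	0.04
s20	t20	120	3	7	0	0.03
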