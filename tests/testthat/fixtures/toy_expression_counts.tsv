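feature	W0_1	W0_2	W0_3	W1_1	W1_2	W1_3	W3_1	W3_2	W3_3	W6_1	W6_2	W6_3	W12_1	W12_2	W12_3	W24_1	W24_2	W24_3
f01	5	0	0	0	6	0	0	0	0	0	0	0	0	0	0	0	0	5
f02	0	0	0	0	0	0	9	9	4	0	0	0	0	0	0	0	0	0
f03	5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	5	5
f04	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
f05	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
f06	0	0	0	0	0	0	0	0	0	4	4	4	0	0	0	0	0	0
f07	0	0	0	50	50	0	0	0	0	0	0	0	0	0	0	0	0	0
f08	0	0	0	0	0	0	5	5	5	0	0	0	0	0	0	0	0	0
f09	4	4	4	4	4	4	4	4	4	4	4	4	5	4	4	4	4	4
f10	0	0	0	20	5	5	0	0	0	0	0	0	0	0	0	0	0	0
f11	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	4	9	9
f12	5	4	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
f13	0	0	0	0	0	0	0	0	0	7	8	9	0	0	0	0	0	0
f14	10	3	10	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
f15	0	0	0	0	0	0	5	5	5	10	10	10	20	20	20	40	40	40
f16	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
f17	10	10	10	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
f18	0	0	0	0	0	0	0	0	0	0	0	0	100	0	0	0	0	0
f19	0	0	0	5	0	0	0	0	0	0	5	0	0	0	5	0	0	0
f20	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	5	5
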