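bin	red5	hongyang_original	hongyang_revised
0-59	6	76	60
60-64	2	23	7
65-69	2	21	15
70-74	5	20	16
75-79	2	36	19
80-84	13	39	28
85-89	17	54	47
90-94	17	72	67
95-99	339	168	231
100	144	29	51
no_match	3	12	9
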