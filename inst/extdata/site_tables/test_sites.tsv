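site	total_n	age_min	age_max	hc_n	gad_n
ABCD	2857	8.91	11	2778	79
Barcelona	69	18	40	46	23
Baylor	226	12	79	128	98
BHRC	767	7.02	21.37	458	309
Boystown	95	13	18	45	50
Chicago-Milad	43	18	59	16	27
Chicago-Phan	141	18	60	41	100
Cincinnati	20	12	18	11	9
CMI-HBN	185	5.01	21.36	97	88
Dresden	93	18	51	46	47
Duke	40	6	10	19	21
SHIP	32	41	70	22	10
Harvard	237	18	40	51	186
Houston	263	8	68.23	251	12
Milan	91	20.89	72.57	61	30
Muenster	53	19	56	29	24
Pittsburgh-Andreescu	64	19	82	26	38
Pittsburgh-Price	69	18	54	0	69
PROTAIA	43	13	22	25	18
Rome	38	18	55	20	18
San-Raffaele	89	23	63	69	20
SDAN	295	8.1	51.14	156	139
SNFA	60	19	50	38	22
Stony-Brook	60	18	49	19	41
UCSD	91	17	53	47	44
WashU	63	8	12	32	31
IOL	63	19	71	21	42
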