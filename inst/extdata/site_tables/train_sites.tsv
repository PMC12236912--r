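site	total_n	mean_age	sd_age	age_min	age_max
HCP	412	28.71	3.67	22	37
HCP-Development	612	14.52	4.04	5.58	21.92
OASIS	334	68.93	9.29	43	93
PING	588	12.42	5.12	3.08	21.67
PNC	1565	15.02	3.66	8.08	23.08
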