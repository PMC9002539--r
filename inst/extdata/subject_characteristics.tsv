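gender	taster_status	n	mean_age_years	mean_bmi
F	NT	7	21.0	24.7
F	ST	5	20.6	22.7
M	NT	3	19.7	24.8
M	ST	5	24.6	25.5
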