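id	status	b73_control	b73_stress	log2fc_b73	rmr6_control	rmr6_stress	log2fc_rmr6
GRMZM6G851663_T01	OK	16.88	65.19	1.95	29.35	85.30	1.54
GRMZM2G320373_T01	OK	4.26	26.37	2.62	8.62	30.94	1.84
GRMZM2G004909_T01	OK	17.25	62.71	1.86	80.40	114.96	0.51
GRMZM2G137329_T01	OK	70.10	199.62	1.51	108.76	194.91	0.84
GRMZM2G170044_T01	OK	10.59	24.52	1.21	17.12	20.30	0.24
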