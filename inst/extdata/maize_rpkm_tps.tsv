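id	status	b73_control	b73_stress	log2fc_b73	rmr6_control	rmr6_stress	log2fc_rmr6
GRMZM2G046615	OK	7.68	45.13	2.55	10,14	25.32	1.32
GRMZM2G046615_T01	NOTEST	0	0.12		0	0.12	
GRMZM2G046615_T01_j_1	NOTEST	0	0.14		0.068	0.04	
GRMZM2G046615_T01_j_2	NOTEST	0	0.14		0	0	
GRMZM2G046615_T01_j_3	OK	7.67	44.73	2.54	10.08	25.15	1.32
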