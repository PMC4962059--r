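id	status	b73_control	b73_stress	log2fc_b73	rmr6_control	rmr6_stress	log2fc_rmr6	log2fc_rmr6_vs_b73
TCONS_00086791	OK	0	1.08	6.77	1.26	1.53	0.28	6.97
TCONS_00073784	OK	0	1.14	6.84	0	3.27	8.36	0
Cluster_t_304	OK	0.94	5.30	2.47	1.08	4.07	2.17	0.2
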