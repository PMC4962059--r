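superfamily	b73_stress_count	rmr6_stress_count	mutant_count
RLG-Gypsy	28	21	42
RLC-Copia	6	7	35
RLX-Unknown LTR	9	2	12
RIL-L1	1	0	0
DTA-hAT	13	3	4
DTC-CACTA	4	4	10
DHH-Helitron	2	3	1
DTM-Mutator	3	0	5
DTH-PIF/Harbinger	3	2	5
DTT-Tc1/Mariner	1	1	1
RST-tRNA	0	0	2
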