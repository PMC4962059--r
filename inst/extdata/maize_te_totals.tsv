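quantity	b73_stress	rmr6_stress	mutant
total_te_related	70	43	117
total_de_transcripts	1094	310	622
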