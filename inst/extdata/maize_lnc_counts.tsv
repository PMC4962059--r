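quantity	value
pot_lncrna_total	36151
sirna_precursor_total	21624
te_derived_total	1140
truly_lncrna_total	13387
lncnat_total	3012
lincrna_total	10375
lincrna_perfect_targets	575
lincrna_near_targets	1780
nat_pairs_coding_mrna	2157
nat_pairs_lncnat_lncnat	750
nat_pairs_sirna_precursor	330
lncnat_len_min	201
lncnat_len_max	3780
lncnat_len_mean	535
lincrna_len_mean	465
lincrna_len_min	201
lincrna_len_max	4179
reference_transcripts_equal	133663
rabt_new_transcripts	25444
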