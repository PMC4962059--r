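transcript_class	coding	pot_lncRNA	lncRNA	siRNA_prec	TEs
Equal	102299	31364	11815	18526	1023
Class J	19796	1603	386	1181	36
Class U	995	1669	625	1005	39
Class O	627	363	96	257	10
Class X	103	288	116	164	8
Previously annotated ncRNAs	517	864	349	491	24
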