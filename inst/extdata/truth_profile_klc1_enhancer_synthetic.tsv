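# Synthetic per-haplotype methylation truth profile for the packaged
# default amplicon (KLC1 fourth-intron enhancer emulation, plus strand).
# Values are the simulator's true methylation probabilities at the sites
# showing haplotype-specific methylation; sites not listed default to
# 0.90 (CpG) and 0.004 (CpH) on each haplotype where the cytosine exists.
coord	strand	AGAGGCD	TAGAATI	AGAGGCI
104060054	+	0.53	0.87	0.58
104060087	+	0.34	0.65	0.36
104060156	+	0.37	0.70	0.41
104060164	+	0.42	0.74	0.46
104060226	+	0.54	0.86	0.55
104060367	+	0.88	0.01	0.84
104060373	+	0.03	0.01	0.06
104060378	+	0.04	0.98	0.12
104060380	+	0.06	0.00	0.03
104060381	+	0.08	0.00	0.04
104060384	+	0.89	0.00	0.89
104060386	+	0.04	0.01	0.03
104060389	+	0.05	0.02	0.06
104060390	+	0.05	0.01	0.05
104060391	+	0.91	0.04	0.92
104060421	+	0.06	0.97	0.85
104060427	+	0.92	0.99	0.93
104060464	+	0.95	0.99	0.94
104060678	+	0.65	0.84	0.76
104060845	+	0.87	0.94	0.87
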