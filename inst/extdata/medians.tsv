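route	scenario	median_auc	interval_low	interval_high	printed_increase_pct
iv	healthy	312.4	271.06	372.41	NA
iv	cp_a	476.46	104.55	1552.99	34.43
iv	cp_b	801.90	171.74	2185.99	61.04
iv	cp_c	1208.94	369.41	3067.14	74.16
oral	healthy	260.1	246.96	280.70	NA
oral	cp_a	444.61	80.22	1575.57	41.50
oral	cp_b	773.84	188.39	2088.88	66.40
oral	cp_c	1114.82	296.27	3423.62	76.70
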