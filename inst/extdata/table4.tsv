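study_id	route	dose	dose_unit	infusion_min	n	n_female	age_min	age_max	age_mean	age_sd	wt_min	wt_max	wt_mean	wt_sd	population
iv1	iv	8	mg	15	32	0	18	40	NA	NA	58.3	95.8	NA	NA	healthy
iv2	iv	8	mg	5	6	2	19	23	NA	NA	NA	NA	NA	NA	healthy
iv3	iv	8	mg	5	6	2	32	43	NA	NA	50	80	NA	NA	healthy
iv4	iv	8	mg	15	6	0	19	35	NA	NA	55.5	90.5	NA	NA	healthy
iv5	iv	0.15	mg_per_kg	15	11	5	NA	NA	31	7	NA	NA	66.1	8.5	healthy
po1	oral	24	mg	NA	12	6	NA	NA	NA	NA	NA	NA	NA	NA	healthy
po2	oral	8	mg	NA	22	11	18	41	NA	NA	49	94	NA	NA	healthy
po3	oral	8	mg	NA	24	0	19	39	NA	NA	60	90	NA	NA	healthy
po4	oral	8	mg	NA	11	5	NA	NA	31	7	NA	NA	66.1	8.5	healthy
po5	oral	8	mg	NA	32	0	18	40	NA	NA	58.3	95.8	NA	NA	healthy
cir	iv	8	mg	5	19	8	20	69	NA	NA	NA	NA	NA	NA	disease
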