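study_id	route	parameter	observed	predicted	printed_ratio
iv1	iv	auc_0inf	246.5	271.06	0.91
iv2	iv	auc_0inf	279	324.87	0.86
iv3	iv	auc_0inf	257	315.18	0.82
iv4	iv	auc_0inf	313	278.54	1.12
iv5	iv	auc_0inf	435.46	372.41	1.17
iv1	iv	cmax	102.5	170.69	0.60
iv2	iv	cmax	161	344.15	0.47
iv3	iv	cmax	343	315.95	1.09
iv4	iv	cmax	159	166.97	0.95
iv5	iv	cmax	170	225.86	0.75
iv1	iv	cl	7.41	6.73	1.10
iv2	iv	cl	6.54	5.70	1.15
iv3	iv	cl	7.10	5.70	1.25
iv4	iv	cl	6.7	6.52	1.03
iv5	iv	cl	5.81	6.76	0.86
po1	oral	auc_0inf	805.9	777.09	1.04
po2	oral	auc_0inf	244.496	280.70	0.87
po3	oral	auc_0inf	246.1	247.22	1.00
po4	oral	auc_0inf	209.27	266.78	0.78
po5	oral	auc_0inf	168.8	246.96	0.68
po1	oral	cmax	94.6	82.81	1.14
po2	oral	cmax	36.113	30.69	1.18
po3	oral	cmax	26.3	26.68	0.99
po4	oral	cmax	32.57	29.34	1.11
po5	oral	cmax	26.4	27.73	0.95
po1	oral	cl	8.64	7.02	1.23
po2	oral	cl	8.06	6.52	1.24
po3	oral	cl	7.42	7.31	1.01
po4	oral	cl	8.9	7.47	1.19
po5	oral	cl	10.8	7.28	1.48
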