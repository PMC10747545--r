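organ	volume_l	flow_l_min	f_water	f_nlipid	f_plipid
lung	0.50	6.50	0.811	0.0030	0.0090
heart	0.33	0.24	0.758	0.0115	0.0166
brain	1.45	0.70	0.770	0.0510	0.0565
muscle	29.00	0.75	0.760	0.0220	0.0072
adipose	14.50	0.26	0.180	0.7900	0.0020
skin	3.30	0.30	0.718	0.0284	0.0111
bone	10.50	0.25	0.439	0.0174	0.0016
liver	1.80	0.30	0.751	0.0348	0.0252
gut	1.65	0.90	0.718	0.0487	0.0163
spleen	0.15	0.30	0.788	0.0201	0.0198
kidney	0.31	1.10	0.783	0.0207	0.0162
rest-of-body	0.90	1.40	0.760	0.0220	0.0072
arterial blood	1.80	NA	NA	NA	NA
venous blood	3.50	NA	NA	NA	NA
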