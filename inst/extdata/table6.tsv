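parameter	control	cp_a	cp_b	cp_c
functional_liver_mass	2.38	0.69	0.55	0.28
cyp3a4	4.32	0.589	0.40	0.40
cyp1a2	1.80	0.63	0.26	0.12
albumin	1	0.84	0.69	0.53
hematocrit	0.47	0.39	0.37	0.35
portal_flow	1.21	0.40	0.36	0.04
hepatic_arterial_flow	17.94	1.30	2.30	3.40
other_organs_flow	NA	1.75	2.25	2.75
renal_flow	302.71	0.88	0.65	0.48
gfr	116	0.70	0.58	0.55
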