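parameter	value
molecular_weight_g_mol	293.4
log_p	2.25
binding_protein	albumin
solubility_mg_l	0.36
pka_base	7.40
specific_intestinal_permeability_cm_min	2.24e-5
specific_organ_permeability_cm_min	8.02e-3
fu_plasma	0.27
partition_model	poulin_theil
cellular_permeability_model	standard
clint_cyp1a2_l_min	0.21
clint_cyp3a4_l_min	0.03
renal_clearance_ml_min_kg	0.13
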