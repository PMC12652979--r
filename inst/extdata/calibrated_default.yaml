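schema_version: 1
variant: calibrated_default
aut_pool: conserved
UPR_T: 1.0
BCL2_T: 1.0
AUT_T: 1.0
APO_T: 1.0
ka_upr: 0.05
ki_upr: 1.0
ka_bcl2: 0.5
ki_bcl2: 0.05
upr_on_bcl2: 3.0
apo_on_bcl2: 3.0
ks_aut: 0.01
kaua_base: 0.45
tg_on_aut: 1.0
ki_aut: 0.05
bcl2_on_aut: 0.8
apo_on_aut: 0.45
cleave_rate: 0.4
kd_auti: 0.2
J_aut_act: 0.05
J_aut_in: 0.05
ks_apo: 0.228
auti_on_apo: 0.24
tg_on_apo: 1.2
dtt_on_apo: 1.2
ki_apo: 0.015
bcl2_on_apo: 0.6
aut_on_apo: 0.228
J_apo_act: 0.05
J_apo_in: 0.02
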