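# ER stress decision network: UPR -| BCL2 -| {AUT, APO}; AUT -| APO;
# APO cleaves AUT -> AUTI; AUTI -> APO; APO cleaves BCL2.
par UPR_T=1
par BCL2_T=1
par AUT_T=1
par APO_T=1
par ka_upr=0.050000000000000003
par ki_upr=1
par ka_bcl2=0.5
par ki_bcl2=0.050000000000000003
par upr_on_bcl2=3
par apo_on_bcl2=3
par ks_aut=0.01
par kaua_base=0.45000000000000001
par tg_on_aut=1
par ki_aut=0.050000000000000003
par bcl2_on_aut=0.80000000000000004
par apo_on_aut=0.45000000000000001
par cleave_rate=0.40000000000000002
par kd_auti=0.20000000000000001
par J_aut_act=0.050000000000000003
par J_aut_in=0.050000000000000003
par ks_apo=0.22800000000000001
par auti_on_apo=0.23999999999999999
par tg_on_apo=1.2
par dtt_on_apo=1.2
par ki_apo=0.014999999999999999
par bcl2_on_apo=0.59999999999999998
par aut_on_apo=0.22800000000000001
par J_apo_act=0.050000000000000003
par J_apo_in=0.02
par stress=0
par tg=0
par dtt=0
par kaua_mult=1
upr'=ka_upr*stress*(UPR_T-upr)-ki_upr*upr
bcl2'=ka_bcl2*(BCL2_T-bcl2)-(ki_bcl2+upr_on_bcl2*upr+apo_on_bcl2*apo_a)*bcl2
aut_a'=(ks_aut+kaua_base*kaua_mult+tg_on_aut*tg)*(AUT_T-aut_a-aut_i)/(J_aut_act+AUT_T-aut_a-aut_i)-(ki_aut+bcl2_on_aut*bcl2+apo_on_aut*apo_a)*aut_a/(J_aut_in+aut_a)-cleave_rate*apo_a*aut_a
aut_i'=cleave_rate*apo_a*aut_a-kd_auti*aut_i
apo_a'=(ks_apo+auti_on_apo*aut_i+tg_on_apo*tg+dtt_on_apo*dtt)*(APO_T-apo_a)/(J_apo_act+APO_T-apo_a)-(ki_apo+bcl2_on_apo*bcl2+aut_on_apo*aut_a)*apo_a/(J_apo_in+apo_a)
init upr=0 bcl2=0.9 aut_a=0.05 aut_i=0 apo_a=0.01
@ total=200,meth=stiff
done
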