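scenario,genotype,regimen,metric,gm_mg_per_L,cv_pct
nonnull_240QD,non-null,240QD,Ctrough,0.0962,64.1
nonnull_240QD,non-null,240QD,Caverage,0.174,42.5
null_240QD,null,240QD,Ctrough,0.206,56.2
null_240QD,null,240QD,Caverage,0.310,42.5
null_160QD,null,160QD,Ctrough,0.138,56.0
null_160QD,null,160QD,Caverage,0.207,42.5
null_240QOD,null,240QOD,Ctrough,0.0864,64.0
null_240QOD,null,240QOD,Caverage,0.155,42.5
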