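group,tissue,route,tmax_min,cmax_ng_ml,ke_per_min,t_half_min,auc_ng_ml_min,conc_ratio_30min,auc_ratio
solution,brain,IV,30,780,0.005,128.5,74944,0.26,0.24
solution,blood,IV,15,4600,0.017,41.5,313493,,
solution,brain,IN,45,748,0.005,144.6,137275,2.14,0.99
solution,blood,IN,45,1000,0.009,75.1,139171,,
coated_carrier,brain,IN,120,1033,0.003,247.2,469403,4.56,1.22
coated_carrier,blood,IN,120,1639,0.005,127.8,385609,,
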