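preparation,jss_ug_cm2_h,cumulative_12h_ug_cm2,papp_cm_h,percent_permeated
coated_carrier,10.63,472.8,0.01063,78.8
solution,5.79,271.2,0.00579,45.2
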