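species,property,value,unit
BSA,D,5.9e-7,cm2_per_s
BSA,s,4.5,S
BSA,eta_intr,0.041,dL_per_g
BSA,M,66500,Da
BSA,vbar,0.733,cm3_per_g
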