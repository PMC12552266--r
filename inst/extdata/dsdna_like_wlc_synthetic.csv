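species,radius,value
sp01,aG,7.546808678480314e-6
sp02,aG,1.1968536385090022e-5
sp03,aG,1.529159631635909e-5
sp04,aG,1.8047638031571632e-5
sp05,aG,2.0448884603829642e-5
sp06,aG,2.2602749910997437e-5
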