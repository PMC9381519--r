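sla,n_patients
HSC-L,18
MPP-L,458
CMP-L,630
GMP-L,360
GP-L,119
MP-L,502
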