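gene,sla,mutated,tested
CEBPA,HSC-L,0,6
CEBPA,MPP-L,1,163
CEBPA,CMP-L,9,248
CEBPA,GMP-L,41,125
CEBPA,GP-L,4,59
CEBPA,MP-L,14,264
DNMT3A,HSC-L,0,8
DNMT3A,MPP-L,13,163
DNMT3A,CMP-L,32,250
DNMT3A,GMP-L,8,155
DNMT3A,GP-L,6,58
DNMT3A,MP-L,71,250
FLT3-ITD,HSC-L,5,13
FLT3-ITD,MPP-L,40,264
FLT3-ITD,CMP-L,61,399
FLT3-ITD,GMP-L,28,258
FLT3-ITD,GP-L,35,94
FLT3-ITD,MP-L,126,428
FLT3-TKD,HSC-L,1,6
FLT3-TKD,MPP-L,8,159
FLT3-TKD,CMP-L,15,234
FLT3-TKD,GMP-L,8,152
FLT3-TKD,GP-L,4,55
FLT3-TKD,MP-L,21,212
IDH1,HSC-L,0,8
IDH1,MPP-L,10,231
IDH1,CMP-L,29,325
IDH1,GMP-L,12,193
IDH1,GP-L,13,72
IDH1,MP-L,37,291
IDH2,HSC-L,1,8
IDH2,MPP-L,25,231
IDH2,CMP-L,45,325
IDH2,GMP-L,23,193
IDH2,GP-L,17,72
IDH2,MP-L,23,291
NPM1,HSC-L,0,9
NPM1,MPP-L,16,271
NPM1,CMP-L,49,394
NPM1,GMP-L,18,232
NPM1,GP-L,75,94
NPM1,MP-L,269,421
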