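gene,module
NPM1,npm1
DNMT3A,dna_methylation
TET2,dna_methylation
IDH1,dna_methylation
IDH2,dna_methylation
ASXL1,chromatin
ASXL2,chromatin
EZH2,chromatin
KMT2D,chromatin
KDM5A,chromatin
KDM6A,chromatin
EP300,chromatin
BCOR,chromatin
BCORL1,chromatin
PHF6,chromatin
SRSF2,spliceosome
SF3B1,spliceosome
U2AF1,spliceosome
ZRSR2,spliceosome
DHX15,spliceosome
STAG2,cohesin
RAD21,cohesin
SMC1A,cohesin
SMC3,cohesin
RUNX1,transcription_factor
CEBPA,transcription_factor
ETV6,transcription_factor
GATA1,transcription_factor
GATA2,transcription_factor
MGA,transcription_factor
MYC,transcription_factor
ZBTB7A,transcription_factor
FLT3,signaling
FLT3-ITD,signaling
FLT3-TKD,signaling
KIT,signaling
KRAS,signaling
NRAS,signaling
PTPN11,signaling
CBL,signaling
JAK2,signaling
NF1,signaling
CSF3R,signaling
CCND2,signaling
PIGA,signaling
SETBP1,signaling
TP53,tumor_suppressor
WT1,tumor_suppressor
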