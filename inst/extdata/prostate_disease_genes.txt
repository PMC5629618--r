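# Top-30 prostate-cancer-associated genes (published disease-gene list,
# used as Pnet source nodes for the PC-3 worked example).
BCL2
EGFR
PIK3CA
PIK3CB
FSD1L
AR
ERBB2
IL6
PROS1
PSAT1
SOX9
ERBB3
SSTR2
PIK3CG
NPEPPS
TP53
E2F1
PIK3CD
NKX3-1
FOLH1
MAGEA11
FOXA1
CSF2
FSD1
GLIPR1
KLF6
BMP7
KLK3
NUSAP1
PLAG1
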