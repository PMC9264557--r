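# Synthetic subset of immune-annotated gene symbols for examples and tests.
# Includes every gene of the packaged 17-pair signature plus additional
# well-known immune genes; NOT the full immune-gene repository list.
FAM3D
FABP3
APOD
PTGDS
IDO1
CCL19
PLA2G2A
PLAU
DEFB1
MMP9
SLURP1
SORT1
IGHG4
ULBP2
TYMP
DES
OASL
SPP1
CLDN4
IGHG2
TNFRSF12A
TNC
RSAD2
TPM2
STAT1
TAP1
CXCL11
IL1A
IL6
IL10
TNF
IFNG
CXCL9
CXCL10
CCL2
CCL5
CD274
PDCD1
CTLA4
FOXP3
GZMB
PRF1
TLR4
TLR9
NLRP3
C3
CFB
HLA-A
HLA-B
HLA-DRA
B2M
TGFB1
VEGFA
EGFR
CD8A
CD4
MS4A1
NCAM1
KLRD1
LAG3
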