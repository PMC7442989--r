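population	super_population
YRI	AFR
LWK	AFR
GWD	AFR
MSL	AFR
ESN	AFR
ASW	AFR
ACB	AFR
MXL	AMR
PUR	AMR
CLM	AMR
PEL	AMR
CHB	EAS
JPT	EAS
CHS	EAS
CDX	EAS
KHV	EAS
CEU	EUR
TSI	EUR
FIN	EUR
GBR	EUR
IBS	EUR
GIH	SAS
PJL	SAS
BEB	SAS
STU	SAS
ITU	SAS
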