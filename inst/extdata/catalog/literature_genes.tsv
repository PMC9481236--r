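symbol	models	synonyms
FGFR2	AD	
FGFR3	AD	
TWIST1	AD	
EFNB1	XLD	
TCF12	AD	
SKI	AD	
RAB23	AR	
FGFR1	AD	
TGFBR2	AD	
POR	AR	
SMAD3	AD	
ERF	AD	
TGFBR1	AD	
MSX2	AD	
RECQL4	AR	
TGFB2	AD	
IFT43	AR	
ANKH	AD	
H1-4	AD	HIST1H1E
EIF5A	AD	
ZIC1	AD	
SOX6	AD	
NFIA	AD	
ARID1B	AD	
DIAPH1	AD,AR	
BRWD3	XLR	
EVC	AD,AR	
ZNF462	AD	
SOST	AD,AR	
SHROOM4	XLR	
AMER1	XLD,XLR	WTX
AFF2	XLR	FMR2
BCORL1	XLR	
IL11RA	AR	
DNAH11	AR	
CDC45	AR	
SNRPB	AD	
APC	AD	
EVC2	AR	
RUNX2	AD	
ALX4	AD	
GLI3	AD	
MEGF8	AR	
SMAD6	AD	
BCL11B	AD	
TFAP2B	AD	
GINS2	AR	
IL6ST	AR	
ESCO2	AR	
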