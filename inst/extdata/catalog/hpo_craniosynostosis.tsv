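symbol
FGFR2
FGFR3
TWIST1
TCF12
EFNB1
ERF
SKI
MSX2
ZIC1
IL11RA
ZNF462
CDC45
RUNX2
ALX4
GLI3
MEGF8
SMAD6
BCL11B
TFAP2B
ESCO2
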