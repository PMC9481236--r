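symbol
FGFR2
FGFR3
TWIST1
TCF12
EFNB1
ERF
SKI
RAB23
IL11RA
ZIC1
MSX2
RUNX2
CDC45
ESCO2
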