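symbol
FGFR2
FGFR3
TWIST1
EFNB1
TCF12
SKI
RAB23
FGFR1
TGFBR2
POR
SMAD3
ERF
TGFBR1
MSX2
RECQL4
TGFB2
IFT43
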