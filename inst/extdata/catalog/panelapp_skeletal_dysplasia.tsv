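symbol
EVC
EVC2
SOST
RUNX2
ALX4
GLI3
SOX6
ANKH
RECQL4
TGFB2
SMAD3
TGFBR1
TGFBR2
FGFR1
POR
IFT43
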