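symbol
ANKH
HIST1H1E
EIF5A
SOX6
NFIA
ARID1B
SNRPB
SOST
AMER1
EVC
EVC2
DIAPH1
BRWD3
SHROOM4
AFF2
BCORL1
DNAH11
APC
RECQL4
GINS2
IL6ST
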