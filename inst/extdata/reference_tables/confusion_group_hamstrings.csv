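actual,FGW,US,DS,UW,DW
FGW,74.1,3.7,0,14.8,7.4
US,3.7,88.9,3.7,0,3.7
DS,0,14.8,77.8,0,7.4
UW,18.5,0,3.7,74.1,3.7
DW,18.5,0,14.8,3.7,63
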