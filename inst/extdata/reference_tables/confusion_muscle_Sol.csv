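actual,FGW,US,DS,UW,DW
FGW,55.6,3.7,7.4,25.9,7.4
US,7.4,85.2,3.7,3.7,0.0
DS,11.1,0.0,70.4,0.0,18.5
UW,14.8,3.7,3.7,74.1,3.7
DW,14.8,3.7,22.2,3.7,55.6
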