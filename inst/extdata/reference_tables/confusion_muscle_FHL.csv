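actual,FGW,US,DS,UW,DW
FGW,74.1,0.0,0.0,11.1,14.8
US,3.7,81.5,7.4,0.0,7.4
DS,11.1,7.4,55.6,7.4,18.5
UW,14.8,0.0,3.7,81.5,0.0
DW,22.2,7.4,18.5,7.4,44.4
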