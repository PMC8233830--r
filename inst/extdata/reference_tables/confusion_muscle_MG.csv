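actual,FGW,US,DS,UW,DW
FGW,85.2,0.0,0.0,11.1,3.7
US,3.7,96.3,0.0,0.0,0.0
DS,0.0,0.0,63.0,0.0,37.0
UW,11.1,3.7,0.0,85.2,0.0
DW,14.8,0.0,7.4,0.0,77.8
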