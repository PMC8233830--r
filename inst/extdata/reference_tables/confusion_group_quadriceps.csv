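actual,FGW,US,DS,UW,DW
FGW,77.8,3.7,0.0,3.7,14.8
US,0.0,77.8,0.0,18.5,3.7
DS,7.4,0.0,74.1,3.7,14.8
UW,7.4,14.8,3.7,63.0,11.1
DW,11.1,18.5,14.8,7.4,48.1
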