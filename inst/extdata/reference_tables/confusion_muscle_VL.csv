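actual,FGW,US,DS,UW,DW
FGW,66.7,7.4,7.4,14.8,3.7
US,0.0,77.8,0.0,22.2,0.0
DS,3.7,0.0,55.6,7.4,33.3
UW,11.1,3.7,3.7,33.3,25.9
DW,14.8,3.7,11.1,18.5,51.9
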