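actual,FGW,US,DS,UW,DW
FGW,92.6,0.0,0.0,3.7,3.7
US,0.0,77.8,0.0,22.2,3.7
DS,0.0,0.0,59.3,7.4,33.3
UW,11.1,14.8,0.0,59.3,14.8
DW,3.7,3.7,14.8,22.2,55.6
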