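actual,FGW,US,DS,UW,DW
FGW,74.1,0.0,0.0,7.4,18.5
US,7.4,77.8,7.4,3.7,3.7
DS,0.0,22.2,66.7,0.0,11.1
UW,3.7,7.4,0.0,88.9,0.0
DW,29.6,7.4,3.7,3.7,55.6
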