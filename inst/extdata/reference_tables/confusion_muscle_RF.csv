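actual,FGW,US,DS,UW,DW
FGW,74.1,18.5,0.0,3.7,3.7
US,0.0,92.6,0.0,3.7,3.7
DS,0.0,3.7,55.6,29.6,11.1
UW,3.7,11.1,7.4,55.6,22.2
DW,11.1,3.7,14.8,11.1,59.3
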