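actual,FGW,US,DS,UW,DW
FGW,88.9,0.0,0.0,7.4,3.7
US,7.4,92.6,0.0,0.0,0.0
DS,0.0,3.7,85.2,0.0,11.1
UW,11.1,0.0,0.0,88.9,0.0
DW,7.4,3.7,0.0,0.0,88.9
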