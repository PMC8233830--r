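actual,FGW,US,DS,UW,DW
FGW,70.4,3.7,7.4,14.8,3.7
US,7.4,88.9,0.0,0.0,3.7
DS,7.4,0.0,66.7,3.7,22.2
UW,7.4,0.0,3.7,88.9,0.0
DW,0.0,0.0,25.9,3.7,70.4
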