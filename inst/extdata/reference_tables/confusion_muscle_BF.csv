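actual,FGW,US,DS,UW,DW
FGW,59.3,3.7,18.5,0.0,18.5
US,7.4,63.0,7.4,3.7,18.5
DS,3.7,7.4,70.4,11.1,7.4
UW,7.4,3.7,3.7,85.2,0.0
DW,7.4,14.8,14.8,7.4,55.6
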