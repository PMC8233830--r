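actual,FGW,US,DS,UW,DW
FGW,59.3,11.1,0.0,11.1,18.5
US,3.7,48.1,29.6,3.7,14.8
DS,0.0,3.7,81.5,3.7,11.1
UW,14.8,14.8,7.4,59.3,3.7
DW,7.4,11.1,7.4,7.4,66.7
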