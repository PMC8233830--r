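actual,FGW,US,DS,UW,DW
FGW,25.9,11.1,11.1,25.9,37.0
US,7.4,51.9,29.6,11.1,0.0
DS,18.5,11.1,48.1,11.1,11.1
UW,22.2,11.1,25.9,40.7,0.0
DW,18.5,11.1,11.1,0.0,59.3
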