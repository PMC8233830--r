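experiment,metric,value
all,accuracy,96.3
group_triceps_surae,accuracy,88.9
group_hamstrings,accuracy,75.6
group_quadriceps,accuracy,68.1
group_FHL,accuracy,67.4
group_TA,accuracy,63.0
group_EDL,accuracy,45.2
MG,accuracy,81.5
LG,accuracy,77.0
ST,accuracy,72.6
VM,accuracy,68.9
Sol,accuracy,68.1
RF,accuracy,67.4
FHL,accuracy,67.4
BF,accuracy,66.7
TA,accuracy,63.0
VL,accuracy,57.0
EDL,accuracy,45.2
all,sensitivity_FGW,100
all,sensitivity_US,100
all,sensitivity_DS,96.3
all,sensitivity_UW,96.3
all,sensitivity_DW,88.9
all,specificity_FGW,99.1
all,specificity_US,99.1
all,specificity_DS,99.1
all,specificity_UW,100
all,specificity_DW,99.1
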