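# Reference per-phase test accuracy [%] of the optimally parameterised model
# on the held-out subject.
phase,accuracy
SW,91.39
HS,85.08
FC,85.45
HO,83.82
Total,86.43
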