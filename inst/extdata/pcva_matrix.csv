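true_cause,Stroke,Diabetes,Other
Stroke,123,18,125
Diabetes,58,6,55
Other,83,95,2112
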