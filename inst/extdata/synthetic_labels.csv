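death_id,true_cause,predicted_cause
synth_000001,Stroke,Stroke
synth_000002,Stroke,Stroke
synth_000003,Other,Other
synth_000004,Other,Diabetes
synth_000005,Other,Other
synth_000006,Other,Other
synth_000007,Other,Other
synth_000008,Other,Stroke
synth_000009,Other,Other
synth_000010,Other,Diabetes
synth_000011,Other,Other
synth_000012,Other,Diabetes
synth_000013,Stroke,Stroke
synth_000014,Other,Other
synth_000015,Other,Other
synth_000016,Stroke,Diabetes
synth_000017,Diabetes,Diabetes
synth_000018,Other,Other
synth_000019,Other,Other
synth_000020,Other,Diabetes
synth_000021,Stroke,Stroke
synth_000022,Other,Diabetes
synth_000023,Diabetes,Stroke
synth_000024,Stroke,Stroke
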