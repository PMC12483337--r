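device,wear_time_h,q1,q2,q3,q4,q5,q6
criterion,24,3,2,3,2,3,2
wearable_wrist,24,4,4,4,3,4,4
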