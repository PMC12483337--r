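"sleep_onset_s","wake_s","notes"
45000,77400,"bedtime"
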