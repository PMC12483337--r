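id: EX01
age_years: 11.5
sex: female
height_m: 1.52
weight_kg: 43.9
bmi_kg_m2: 19.0
wrist_circumference_cm: 14.8
fitzpatrick: III
indication: arrhythmia
recording_start: '2024-03-01T10:00:00+01:00'
duration_s: 86400.0
accel_scale_divisor: 512.0
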