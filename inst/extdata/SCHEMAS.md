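# On-disk schemas

One directory per participant; a cohort is a directory of participant
directories plus `ledger.csv` when simulated. All CSVs are RFC-4180, UTF-8,
with a mandatory header row. Timestamps are numeric seconds since the
participant's recording start; the start itself is an ISO-8601 field in
`meta.yaml`, which keeps device clock offsets explicit and read/write round
trips exact.

| file | columns / fields | notes |
|---|---|---|
| `criterion_rr.csv` | `beat_time` (s, strictly increasing), `rr_ms` (> 0) | criterion device's native beat-to-beat output (`example_rr.csv`) |
| `criterion_hr.csv` | `t` (s), `bpm` | alternative 1 Hz criterion export (`example_hr.csv` shows the HR schema) |
| `<device>_hr.csv` | `t` (s), `bpm` | empty field = missing; literal `0` is preserved and classified as underdetected downstream (`example_hr.csv`) |
| `<device>_accel.csv` | `t`, `acc_x`, `acc_y`, `acc_z` | raw counts or g; counts-per-g divisor recorded in `meta.yaml` (`example_accel.csv`) |
| `diary.csv` | `sleep_onset_s`, `wake_s`, `notes` | one row per sleep episode, onset < wake (`example_diary.csv`) |
| `meta.yaml` | `id`, `age_years` (6-18), `sex`, `height_m`, `weight_kg`, `bmi_kg_m2` (consistent within 1%), `wrist_circumference_cm`?, `fitzpatrick` (I-VI)?, `indication` (CHD / arrhythmia / symptoms), `recording_start`, `duration_s`, `accel_scale_divisor` | `example_meta.yaml` |
| `questionnaire.csv` | `device` (criterion / wearable_wrist / wearable_shirt), `wear_time_h`, `q1`..`qK` (Likert 1-5) | one row per device (`example_questionnaire.csv`) |

These are normalized schemas defined by this package, not reproductions of
any vendor portal's export format.
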