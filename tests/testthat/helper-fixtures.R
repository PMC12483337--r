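# Small fixture builders shared across the suite. Everything is generated in
# code at test time; no binary fixtures.

# a clean 1 Hz HR series following a slow sinusoid plus linear trend
make_hr <- function(n = 600, t0 = 0, f = function(t) 80 + 10 * sin(t / 50) + t / 200) {
  t <- seq(t0, t0 + n - 1)
  hr_series(t, f(t), nominal_rate_hz = 1)
}

# paired series built directly from two vectors on a shared grid
make_paired <- function(criterion, wearable,
                        cause = rep("none", length(criterion))) {
  x <- data.frame(t = seq_along(criterion) - 1, criterion_bpm = criterion,
                  wearable_bpm = wearable, missing_cause = cause)
  class(x) <- c("paired_series", "data.frame")
  x
}

make_movement <- function(intensity, t = seq_along(intensity), id = NULL) {
  x <- data.frame(t = t, intensity_g = intensity)
  class(x) <- c("movement_series", "data.frame")
  attr(x, "participant") <- id
  x
}

tiny_meta <- function(id = "P01", age = 10, height = 1.4, weight = 35) {
  list(id = id, age_years = age, sex = "female", height_m = height,
       weight_kg = weight, bmi_kg_m2 = round(weight / height^2, 2),
       wrist_circumference_cm = 15, fitzpatrick = "II", indication = "CHD",
       duration_s = 86400)
}
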