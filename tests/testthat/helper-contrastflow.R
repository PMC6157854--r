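# Shared fixtures: the default calibration and the published
# mean-and-range injection table used for enclosure checks.

default_cal <- calibrate_attenuation()

# Injection-parameter ranges (min, max) by sex x mode x kV for flow
# (mL/s), main bolus (mL) and IDR (gI/s), as printed in the study's
# protocol table.
table3_ranges <- tibble::tribble(
  ~sex, ~mode, ~kv, ~flow_min, ~flow_max, ~bolus_min, ~bolus_max, ~idr_min, ~idr_max,
  "female", "high_pitch", 70, 2.4, 4.0, 19.8, 32.9, 0.7, 1.2,
  "male", "high_pitch", 70, 2.6, 4.4, 21.8, 37.8, 0.8, 1.3,
  "female", "high_pitch", 80, 3.2, 5.2, 26.9, 45.0, 1.0, 1.6,
  "male", "high_pitch", 80, 4.1, 5.5, 34.9, 48.0, 1.2, 1.7,
  "female", "high_pitch", 90, 4.3, 5.4, 37.1, 45.9, 1.3, 1.6,
  "male", "high_pitch", 90, 5.2, 6.7, 46.0, 57.1, 1.6, 2.0,
  "female", "adaptive_sequence", 70, 2.7, 3.8, 27.8, 40.1, 0.8, 1.1,
  "male", "adaptive_sequence", 70, 3.3, 4.5, 33.9, 48.1, 1.0, 1.4,
  "female", "adaptive_sequence", 80, 3.5, 4.2, 35.8, 43.8, 1.1, 1.3,
  "male", "adaptive_sequence", 80, 4.0, 5.4, 41.7, 58.0, 1.2, 1.6,
  "female", "adaptive_sequence", 90, 4.5, 5.8, 46.9, 61.7, 1.4, 1.7,
  "male", "adaptive_sequence", 90, 5.5, 6.0, 59.1, 62.9, 1.7, 1.8
)

# a tiny valid patient table
tiny_patients <- function() {
  tibble::tibble(
    id = c("A", "B", "C"),
    sex = c("M", "F", "F"),
    height_m = c(1.80, 1.65, 1.70),
    weight_kg = c(80, 60, 72),
    heart_rate_bpm = c(64, 58, 82)
  )
}
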