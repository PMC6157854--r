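# Objective image-quality metrics and a synthetic ROI generator.
#
# Per coronary segment (AHA 17-segment model) an ROI measurement carries
# the intravascular mean attenuation and its SD (image noise) plus the
# epicardial-fat mean and SD. CNR = (vessel - fat) / fat SD;
# SNR = vessel / vessel SD. A segment is diagnostic by attenuation when
# its mean is >= 300 HU (inclusive) and by contrast when CNR > 10
# (strict).

# AHA 17-segment model vessel assignment: RCA 1-4 and 16, left main 5,
# LAD 6-10 (incl. diagonals 9-10), circumflex 11-15 (incl. marginals),
# ramus intermedius 17.
aha_vessels <- c(
  "RCA", "RCA", "RCA", "RCA", "LM", "LAD", "LAD", "LAD", "LAD", "LAD",
  "Cx", "Cx", "Cx", "Cx", "Cx", "RCA", "RI"
)

#' AHA 17-segment reference table
#'
#' @return Tibble with `segment_id` (1-17) and `vessel`
#'   (RCA/LM/LAD/Cx/RI).
#' @export
aha_segments <- function() {
  tibble(segment_id = 1:17, vessel = aha_vessels)
}

#' Contrast-to-noise ratio
#'
#' `(vessel_mean - fat_mean) / fat_sd`.
#'
#' @param vessel_mean Intravascular mean attenuation, HU.
#' @param fat_mean Epicardial fat mean attenuation, HU.
#' @param fat_sd SD of the fat attenuation, HU (must be > 0).
#' @return CNR (unitless).
#' @export
#' @examples
#' cnr(360, -80, 30)
cnr <- function(vessel_mean, fat_mean, fat_sd) {
  if (any(!is.na(fat_sd) & fat_sd <= 0)) {
    abort("Field `fat_sd` must be strictly positive.",
      class = "contrastflow_validation_error")
  }
  (vessel_mean - fat_mean) / fat_sd
}

#' Signal-to-noise ratio
#'
#' `vessel_mean / vessel_sd`, where the vessel SD is the image noise.
#'
#' @param vessel_mean Intravascular mean attenuation, HU.
#' @param vessel_sd SD of the intravascular attenuation, HU (> 0).
#' @return SNR (unitless).
#' @export
#' @examples
#' snr(350, 35)
snr <- function(vessel_mean, vessel_sd) {
  if (any(!is.na(vessel_sd) & vessel_sd <= 0)) {
    abort("Field `vessel_sd` must be strictly positive.",
      class = "contrastflow_validation_error")
  }
  vessel_mean / vessel_sd
}

#' Diagnostic image-quality thresholds
#'
#' @param attenuation_min_hu Minimum diagnostic attenuation (default
#'   300 HU, inclusive).
#' @param cnr_min Minimum diagnostic CNR (default 10, strict).
#' @return An `iq_thresholds` list.
#' @export
iq_thresholds <- function(attenuation_min_hu = 300, cnr_min = 10) {
  if (attenuation_min_hu <= 0 || cnr_min <= 0) {
    abort("Thresholds must be strictly positive.",
      class = "contrastflow_validation_error")
  }
  structure(list(attenuation_min_hu = attenuation_min_hu,
    cnr_min = cnr_min), class = "iq_thresholds")
}

#' Compute CNR/SNR and diagnostic flags for segment ROIs
#'
#' Pure and idempotent: recomputes `cnr`, `snr`,
#' `diagnostic_attenuation` (vessel mean >= threshold, inclusive) and
#' `diagnostic_cnr` (CNR strictly > threshold) from the ROI columns.
#' Non-assessable segments (if an `assessable` column is present) get
#' `NA` metrics and `FALSE` flags.
#'
#' @param segments Tibble with `vessel_mean_hu`, `vessel_sd_hu`,
#'   `fat_mean_hu`, `fat_sd_hu` and optionally `assessable`.
#' @param thresholds An [iq_thresholds()].
#' @return The table with metric and flag columns (re)computed.
#' @export
classify_iq <- function(segments, thresholds = iq_thresholds()) {
  stopifnot(inherits(thresholds, "iq_thresholds"))
  segments <- as_tibble(segments)
  if (!"assessable" %in% names(segments)) segments$assessable <- TRUE
  ok <- segments$assessable
  segments |>
    mutate(
      cnr = ifelse(ok,
        cnr(.data$vessel_mean_hu, .data$fat_mean_hu, .data$fat_sd_hu),
        NA_real_),
      snr = ifelse(ok,
        snr(.data$vessel_mean_hu, .data$vessel_sd_hu), NA_real_),
      diagnostic_attenuation = ok &
        .data$vessel_mean_hu >= thresholds$attenuation_min_hu,
      diagnostic_cnr = ok & !is.na(.data$cnr) &
        .data$cnr > thresholds$cnr_min
    )
}

#' Default per-segment non-assessability rates
#'
#' Distal and side-branch segments drop out most often (segment 4:
#' 6.1%, 9: 10.5%, 10: 7.9%, 12: 13.2%, 13: 4.4%, 14: 13.2%); all other
#' segments default to 1%.
#'
#' @return Named numeric vector of length 17 (probabilities).
#' @export
default_segment_dropout <- function() {
  d <- rep(0.01, 17)
  d[c(4, 9, 10, 12, 13, 14)] <- c(0.061, 0.105, 0.079, 0.132, 0.044, 0.132)
  setNames(d, as.character(1:17))
}

#' Noise configuration for the synthetic ROI generator
#'
#' @param sigma_hu Between-segment SD of intravascular attenuation about
#'   the model prediction, HU.
#' @param noise_mean_hu Named vector of mean image noise by kV (HU).
#' @param noise_default_hu Mean image noise for unlisted kV.
#' @param noise_sd_hu SD of the image-noise draw.
#' @param fat_mean_hu,fat_sd_hu Epicardial fat attenuation prior (HU).
#' @param fat_noise_mean_hu,fat_noise_sd_hu Prior for the fat-ROI SD.
#' @param dropout Per-segment non-assessability probabilities
#'   (length 17).
#' @return An `iq_noise_config` list.
#' @export
iq_noise_config <- function(sigma_hu = 43,
                            noise_mean_hu = c("70" = 42, "80" = 41, "90" = 43),
                            noise_default_hu = 43,
                            noise_sd_hu = 6,
                            fat_mean_hu = -80, fat_sd_hu = 15,
                            fat_noise_mean_hu = 30, fat_noise_sd_hu = 5,
                            dropout = default_segment_dropout()) {
  if (length(dropout) != 17 || any(dropout < 0 | dropout > 1)) {
    abort("`dropout` must be 17 probabilities in [0, 1].",
      class = "contrastflow_validation_error")
  }
  structure(list(sigma_hu = sigma_hu, noise_mean_hu = noise_mean_hu,
    noise_default_hu = noise_default_hu, noise_sd_hu = noise_sd_hu,
    fat_mean_hu = fat_mean_hu, fat_sd_hu = fat_sd_hu,
    fat_noise_mean_hu = fat_noise_mean_hu,
    fat_noise_sd_hu = fat_noise_sd_hu, dropout = dropout),
    class = "iq_noise_config")
}

#' Simulate a 17-segment ROI set for one scan
#'
#' Segment attenuation is drawn about the calibrated model prediction
#' (`predicted_attenuation(flow, kv, bv, cal)`) with SD `sigma_hu`;
#' image noise about the kV-specific mean; epicardial fat from its
#' prior. Distal-segment dropout marks segments non-assessable.
#'
#' @param flow_ml_s Injected flow, mL/s.
#' @param kv Tube voltage, kV.
#' @param bv_l Patient blood volume, litres.
#' @param cal A `cm_calibration`.
#' @param noise An [iq_noise_config()].
#' @param seed Optional integer seed.
#' @return A 17-row tibble: `segment_id, vessel, assessable,
#'   vessel_mean_hu, vessel_sd_hu, fat_mean_hu, fat_sd_hu`.
#' @export
simulate_roi_set <- function(flow_ml_s, kv, bv_l, cal,
                             noise = iq_noise_config(), seed = NULL) {
  stopifnot(inherits(noise, "iq_noise_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  mu <- predicted_attenuation(flow_ml_s, kv, bv_l, cal)
  nm <- noise$noise_mean_hu[as.character(kv)]
  if (is.na(nm)) nm <- noise$noise_default_hu
  pos <- function(x, floor = 1) pmax(x, floor)
  aha_segments() |>
    mutate(
      assessable = runif(17) >= noise$dropout,
      vessel_mean_hu = rnorm(17, mu, noise$sigma_hu),
      vessel_sd_hu = pos(rnorm(17, nm, noise$noise_sd_hu)),
      fat_mean_hu = rnorm(17, noise$fat_mean_hu, noise$fat_sd_hu),
      fat_sd_hu = pos(rnorm(17, noise$fat_noise_mean_hu,
        noise$fat_noise_sd_hu))
    )
}

#' Simulate segment ROIs for a whole protocol table
#'
#' @param protocols Output of [generate_protocol()] (or the `protocols`
#'   element of a `cm_study`).
#' @param cal A `cm_calibration`.
#' @param noise An [iq_noise_config()].
#' @param seed Optional integer seed for the whole cohort.
#' @param thresholds An [iq_thresholds()] used for the diagnostic flags.
#' @return Tibble of 17 rows per patient with `patient_id` plus the
#'   [simulate_roi_set()] columns, classified via [classify_iq()].
#' @export
simulate_cohort_iq <- function(protocols, cal, noise = iq_noise_config(),
                               seed = NULL,
                               thresholds = iq_thresholds()) {
  if (!is.null(seed)) withr::local_seed(seed)
  out <- purrr::pmap(
    list(protocols$id, protocols$flow_ml_s, protocols$kv,
      protocols$bv_l),
    function(id, flow, kv, bv) {
      mutate(simulate_roi_set(flow, kv, bv, cal, noise),
        patient_id = id, .before = 1)
    }
  )
  classify_iq(bind_rows(out), thresholds)
}

#' Cohort image-quality summary
#'
#' Per-patient "overall" quality is the simple mean across that
#' patient's assessable segments; a patient is diagnostic when that
#' overall attenuation meets the threshold. Patients with zero
#' assessable segments are excluded with a warning.
#'
#' @param segments Segment tibble (e.g. from [simulate_cohort_iq()] or
#'   [read_segments()]) with a `patient_id` column.
#' @param thresholds An [iq_thresholds()].
#' @return A `cm_iq_summary`: list of `per_patient` and `overall`
#'   tibbles.
#' @export
cohort_iq_summary <- function(segments, thresholds = iq_thresholds()) {
  if (nrow(segments) == 0) {
    abort("`segments` is empty.", class = "contrastflow_validation_error")
  }
  segments <- classify_iq(segments, thresholds)
  per_patient <- segments |>
    filter(.data$assessable) |>
    group_by(.data$patient_id) |>
    summarise(
      n_assessable = dplyr::n(),
      mean_hu = mean(.data$vessel_mean_hu),
      mean_noise_hu = mean(.data$vessel_sd_hu),
      mean_cnr = mean(.data$cnr),
      mean_snr = mean(.data$snr),
      .groups = "drop"
    ) |>
    mutate(
      diagnostic_attenuation =
        .data$mean_hu >= thresholds$attenuation_min_hu,
      diagnostic_cnr = .data$mean_cnr > thresholds$cnr_min
    )
  dropped <- setdiff(unique(segments$patient_id), per_patient$patient_id)
  if (length(dropped) > 0) {
    warn(sprintf(
      "%d patient(s) excluded from the summary: no assessable segments.",
      length(dropped)
    ))
  }
  overall <- tibble(
    n_patients = nrow(per_patient),
    n_segments = nrow(segments),
    pct_assessable = 100 * mean(segments$assessable),
    pct_patients_diagnostic_hu =
      100 * mean(per_patient$diagnostic_attenuation),
    pct_patients_diagnostic_cnr = 100 * mean(per_patient$diagnostic_cnr),
    pct_segments_diagnostic_hu =
      100 * mean(segments$diagnostic_attenuation[segments$assessable]),
    pct_segments_diagnostic_cnr =
      100 * mean(segments$diagnostic_cnr[segments$assessable])
  )
  structure(list(per_patient = per_patient, overall = overall),
    class = "cm_iq_summary")
}

#' @export
print.cm_iq_summary <- function(x, ...) {
  cat("<cm_iq_summary>\n")
  print(x$overall)
  invisible(x)
}

#' Read a segment ROI CSV
#'
#' Columns `patient_id,segment_id,vessel,vessel_mean_hu,vessel_sd_hu,
#' fat_mean_hu,fat_sd_hu,likert` (`likert` optional and stored as
#' supplied, never generated).
#'
#' @param path CSV path.
#' @return Segment tibble.
#' @export
read_segments <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("patient_id", "segment_id", "vessel_mean_hu",
    "vessel_sd_hu", "fat_mean_hu", "fat_sd_hu")
  for (col in needed) {
    if (!col %in% names(raw)) {
      abort(paste0("Field `", col, "` is missing from the segment table."),
        class = "contrastflow_validation_error")
    }
  }
  if (any(raw$segment_id < 1 | raw$segment_id > 17)) {
    abort("Field `segment_id` must lie in 1..17.",
      class = "contrastflow_validation_error")
  }
  as_tibble(raw)
}
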