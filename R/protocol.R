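# Injection-protocol generation: the programmatic equivalent of the
# locked worksheet technicians used at the scanner.

#' Assign the ECG-triggered scan mode from heart rate
#'
#' Heart rate <= 70 bpm selects the high-pitch spiral mode (scan time
#' 8 s); 70-90 bpm the adaptive-sequence mode (10 s). Above 90 bpm a
#' retrospective helical protocol would be used, which this package does
#' not model.
#'
#' @param heart_rate_bpm Heart rate(s) in beats per minute.
#' @return Character vector: `"high_pitch"` or `"adaptive_sequence"`.
#' @export
#' @examples
#' assign_scan_mode(c(64, 70, 85))
assign_scan_mode <- function(heart_rate_bpm) {
  if (anyNA(heart_rate_bpm)) {
    abort(paste0(
      "Missing heart rate: supply `heart_rate_bpm` or choose the scan ",
      "mode explicitly."
    ), class = "contrastflow_validation_error")
  }
  if (any(heart_rate_bpm > 90)) {
    abort(paste0(
      "Heart rate above 90 bpm requires a retrospective helical ",
      "protocol, which is out of scope."
    ), class = "contrastflow_scope_error")
  }
  ifelse(heart_rate_bpm <= 70, "high_pitch", "adaptive_sequence")
}

#' Default scan time for a mode
#'
#' @param mode `"high_pitch"` (8 s) or `"adaptive_sequence"` (10 s).
#' @return Scan time in seconds.
#' @export
scan_time_for_mode <- function(mode) {
  if (!all(mode %in% c("high_pitch", "adaptive_sequence"))) {
    abort("`mode` must be 'high_pitch' or 'adaptive_sequence'.",
      class = "contrastflow_validation_error")
  }
  ifelse(mode == "high_pitch", 8, 10)
}

#' Iodine delivery rate and total iodine load
#'
#' `IDR = flow x Ic / 1000` in gI/s; `TIL = volume x Ic / 1000` in gI
#' (by convention the total iodine load counts the main bolus only).
#' Both are reported to 0.1 by default, the precision of injector
#' reports.
#'
#' @param flow_ml_s Flow rate, mL/s.
#' @param volume_ml Injected volume, mL.
#' @param agent A [contrast_agent()].
#' @param round Round to 0.1 (default `TRUE`).
#' @return IDR in gI/s, or TIL in gI.
#' @export
#' @examples
#' iodine_delivery_rate(7.0) # 2.1 gI/s
#' iodine_load(25.1) # 7.5 gI
iodine_delivery_rate <- function(flow_ml_s, agent = contrast_agent(),
                                 round = TRUE) {
  x <- flow_ml_s * agent$iodine_mg_ml / 1000
  if (round) round(x, 1) else x
}

#' @rdname iodine_delivery_rate
#' @export
iodine_load <- function(volume_ml, agent = contrast_agent(),
                        round = TRUE) {
  x <- volume_ml * agent$iodine_mg_ml / 1000
  if (round) round(x, 1) else x
}

#' Generate personalised injection protocols
#'
#' For each patient: Nadler blood volume, scan mode from heart rate
#' (unless given), personalised flow rate `F = c_cal * BV * kV`, main
#' bolus = flow x injection time (injection time = scan time + optional
#' buffer), test bolus = flow x `test_bolus_s`, iodine delivery rate
#' `IDR = F * Ic / 1000` (gI/s) and total iodine load
#' `TIL = main bolus * Ic / 1000` (gI, main bolus only — the test bolus
#' is tracked separately).
#'
#' Rounding (when `round = TRUE`): flows to 0.1 mL/s, volumes to 0.1 mL,
#' IDR/TIL to 0.1, matching injector-report precision.
#'
#' @param patients Patient table; needs `sex`, `height_m`, `weight_kg`
#'   and either `heart_rate_bpm` or a `mode` column/argument, plus a `kv`
#'   column or the `kv` argument.
#' @param cal A `cm_calibration` (see [calibrate_attenuation()]).
#' @param kv Tube voltage applied to all patients lacking a `kv` column.
#' @param mode Scan mode applied to all patients lacking a `mode` column;
#'   default derives it from heart rate.
#' @param test_bolus_s Test-bolus duration in seconds (default 2.1 s of
#'   injection at the personalised flow).
#' @param injection_time_buffer_s Extra seconds added to the scan time to
#'   form the injection time (default 0).
#' @param max_flow_ml_s Safety ceiling for an 18-22 G cannula; flows above
#'   it are flagged (column `flow_warning`) and a warning is raised.
#' @param round Apply report rounding (default `TRUE`).
#' @return A tibble with one row per patient: `id, sex, mode, kv, bv_l,
#'   flow_ml_s, test_bolus_ml, main_bolus_ml, injection_time_s, idr_gi_s,
#'   til_g, flow_warning`.
#' @export
#' @examples
#' cal <- calibrate_attenuation()
#' generate_protocol(
#'   data.frame(sex = "M", height_m = 1.80, weight_kg = 80),
#'   cal, kv = 120, mode = "high_pitch"
#' )
generate_protocol <- function(patients, cal, kv = NULL, mode = NULL,
                              test_bolus_s = 2.1,
                              injection_time_buffer_s = 0,
                              max_flow_ml_s = 7.5, round = TRUE) {
  stopifnot(inherits(cal, "cm_calibration"))
  patients <- add_blood_volume(patients)
  if (!"kv" %in% names(patients)) {
    if (is.null(kv)) {
      abort("Tube voltage required: add a `kv` column or pass `kv =`.",
        class = "contrastflow_validation_error")
    }
    patients$kv <- kv
  }
  if (!"mode" %in% names(patients)) {
    if (!is.null(mode)) {
      patients$mode <- mode
    } else {
      if (!"heart_rate_bpm" %in% names(patients)) {
        abort(paste0(
          "Scan mode required: add a `mode` column, pass `mode =`, or ",
          "provide `heart_rate_bpm`."
        ), class = "contrastflow_validation_error")
      }
      patients$mode <- assign_scan_mode(patients$heart_rate_bpm)
    }
  }
  scan_time_for_mode(patients$mode) # validates mode labels
  rnd <- function(x) if (round) round(x, 1) else x

  out <- patients |>
    mutate(
      flow_ml_s = flow_rate(.data$bv_l, .data$kv, cal, round = round),
      injection_time_s = scan_time_for_mode(.data$mode) +
        injection_time_buffer_s,
      main_bolus_ml = rnd(.data$flow_ml_s * .data$injection_time_s),
      test_bolus_ml = rnd(.data$flow_ml_s * test_bolus_s),
      idr_gi_s = iodine_delivery_rate(.data$flow_ml_s, cal$agent,
        round = round),
      til_g = iodine_load(.data$main_bolus_ml, cal$agent, round = round),
      flow_warning = .data$flow_ml_s > max_flow_ml_s
    )
  if (any(out$flow_warning)) {
    warn(sprintf(
      "%d protocol(s) exceed the %g mL/s cannula safety ceiling.",
      sum(out$flow_warning), max_flow_ml_s
    ))
  }
  select(out, "id", "sex", "mode", "kv", "bv_l", "flow_ml_s",
    "test_bolus_ml", "main_bolus_ml", "injection_time_s", "idr_gi_s",
    "til_g", "flow_warning")
}

#' Summarise protocols as a mean-and-range table
#'
#' Groups by scan mode, tube voltage and sex (in that order) and reports
#' mean, min and max for each injection parameter, in the style of a
#' published protocol table. Empty groups simply do not appear.
#'
#' @param protocols Output of [generate_protocol()].
#' @param digits Rounding for the formatted label (default 1).
#' @return A long tibble: `mode, kv, sex, n, parameter, mean, min, max,
#'   label` ordered by mode, kV, sex.
#' @export
protocol_table <- function(protocols, digits = 1) {
  if (nrow(protocols) == 0) {
    abort("`protocols` is empty.", class = "contrastflow_validation_error")
  }
  params <- c("flow_ml_s", "test_bolus_ml", "main_bolus_ml", "til_g",
    "idr_gi_s", "injection_time_s")
  protocols |>
    select("mode", "kv", "sex", dplyr::all_of(params)) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter") |>
    group_by(.data$mode, .data$kv, .data$sex, .data$parameter) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    mutate(
      parameter = factor(.data$parameter, levels = params),
      label = sprintf(
        paste0("%.", digits, "f [%.", digits, "f-%.", digits, "f]"),
        .data$mean, .data$min, .data$max
      )
    ) |>
    arrange(.data$mode, .data$kv, .data$sex, .data$parameter)
}
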