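# First-pass pharmacokinetic attenuation model and its calibration.
#
# The working model: during injection at flow F (mL/s) of an agent with
# iodine concentration Ic (mgI/mL), the intravascular concentration is
#   c(t) = F * Ic / CO * (1 - exp(-CO * t / V)),
# the solution of dc/dt = (F*Ic - CO*c)/V with c(0) = 0, where CO is
# cardiac output (mL/s) and V the effective mixing volume (mL).
# Attenuation is proportional to concentration (HU = k*c), inversely
# proportional to tube voltage, and scaled by patient blood volume:
#   HU(kV) = k * F * Ic / (kV * BV).
# Anchoring this at a reference patient fixes k and yields the linear
# flow rule F = c_cal * BV * kV.

#' Contrast agent
#'
#' @param name Agent label.
#' @param iodine_mg_ml Iodine concentration in mgI/mL, in (100, 450].
#' @return A `contrast_agent` object.
#' @export
#' @examples
#' contrast_agent() # iopromide 300 mgI/mL
contrast_agent <- function(name = "iopromide", iodine_mg_ml = 300) {
  if (!is.numeric(iodine_mg_ml) || length(iodine_mg_ml) != 1 ||
      iodine_mg_ml <= 100 || iodine_mg_ml > 450) {
    abort("Field `iodine_mg_ml` must be a single value in (100, 450].",
      class = "contrastflow_validation_error")
  }
  structure(list(name = name, iodine_mg_ml = iodine_mg_ml),
    class = "contrast_agent")
}

#' @export
print.contrast_agent <- function(x, ...) {
  cat(sprintf("<contrast_agent> %s, %g mgI/mL\n", x$name, x$iodine_mg_ml))
  invisible(x)
}

#' Pharmacokinetic parameters for the concentration model
#'
#' Cardiac output and mixing volume defaults (90 mL/s, 100 mL) are generic
#' adult first-pass values used only by [cm_concentration()]; they do not
#' enter the flow rule.
#'
#' @param flow_ml_s Injection flow rate, mL/s.
#' @param iodine_mg_ml Agent iodine concentration, mgI/mL.
#' @param cardiac_output_ml_s Cardiac output, mL/s.
#' @param mixing_volume_ml Effective mixing volume, mL.
#' @return A named list of class `pk_params`.
#' @export
pk_params <- function(flow_ml_s = 7.0, iodine_mg_ml = 300,
                      cardiac_output_ml_s = 90, mixing_volume_ml = 100) {
  p <- list(flow_ml_s = flow_ml_s, iodine_mg_ml = iodine_mg_ml,
    cardiac_output_ml_s = cardiac_output_ml_s,
    mixing_volume_ml = mixing_volume_ml)
  if (any(unlist(p) <= 0)) {
    abort("All pharmacokinetic parameters must be strictly positive.",
      class = "contrastflow_validation_error")
  }
  structure(p, class = "pk_params")
}

#' Intravascular contrast concentration during injection
#'
#' Closed-form first-pass concentration
#' `c(t) = F*Ic/CO * (1 - exp(-CO*t/V))`: zero at t = 0, monotone
#' increasing, asymptote `F*Ic/CO`.
#'
#' @param t Time since injection start, seconds (vectorised, must be >= 0).
#' @param params A [pk_params()] object.
#' @return Concentration in mgI/mL.
#' @export
#' @examples
#' cm_concentration(10, pk_params())
cm_concentration <- function(t, params = pk_params()) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) {
    abort("Time `t` must be non-negative.",
      class = "contrastflow_validation_error")
  }
  with(params,
    flow_ml_s * iodine_mg_ml / cardiac_output_ml_s *
      (1 - exp(-cardiac_output_ml_s * t / mixing_volume_ml))
  )
}

#' Reference calibration anchor
#'
#' The anchor that fixes the attenuation constant and flow rule: a male
#' patient of 1.80 m and 80 kg (Nadler blood volume 5.319 L) scanned at
#' 120 kV with flow 7.0 mL/s (IDR 2.1 gI/s at 300 mgI/mL) producing a
#' target intravascular attenuation of 350 HU.
#'
#' @param height_m,weight_kg,sex Anchor anthropometrics.
#' @param kv Anchor tube voltage, kV.
#' @param flow_ml_s Anchor flow rate, mL/s.
#' @param target_hu Target attenuation at the anchor, HU.
#' @param idr_gi_s Anchor iodine delivery rate, gI/s (consistency check:
#'   must equal `flow * Ic / 1000` for the configured agent).
#' @return A named list describing the anchor.
#' @export
reference_anchor <- function(height_m = 1.80, weight_kg = 80, sex = "male",
                             kv = 120, flow_ml_s = 7.0, target_hu = 350,
                             idr_gi_s = 2.1) {
  list(height_m = height_m, weight_kg = weight_kg,
    sex = normalize_sex(sex), kv = kv, flow_ml_s = flow_ml_s,
    target_hu = target_hu, idr_gi_s = idr_gi_s)
}

#' Calibrate the attenuation model and flow rule
#'
#' Inserts the anchor patient into the Nadler formula and solves the
#' attenuation model for the constant `k` and the flow-rule constant
#' `c_cal`:
#' `k = target_hu * kv * BV / (flow * Ic)`,
#' `c_cal = flow / (BV * kv)` so that `F = c_cal * BV * kV` returns the
#' anchor flow exactly and `predicted_attenuation()` returns `target_hu`
#' for any patient given their personalised flow.
#'
#' `flow_constant = "legacy"` applies a literal constant of 2e-4 L^-1
#' kV^-1 mL s^-1 instead of the anchor-derived value, for auditing legacy
#' worksheets; it does not reproduce the anchor flow and emits a warning.
#'
#' @param anchor A [reference_anchor()].
#' @param agent A [contrast_agent()].
#' @param flow_constant `"anchor"` (default) or `"legacy"`.
#' @return A `cm_calibration` object with elements `k` (HU per
#'   mgI mL^-1 kV^-1 L^-1 composite), `c_cal`, `anchor` (with its blood
#'   volume), `agent` and `flow_constant`.
#' @export
#' @examples
#' cal <- calibrate_attenuation()
#' cal$c_cal # 0.010967
calibrate_attenuation <- function(anchor = reference_anchor(),
                                  agent = contrast_agent(),
                                  flow_constant = c("anchor", "legacy")) {
  flow_constant <- match.arg(flow_constant)
  if (anchor$target_hu <= 0) {
    abort("Anchor `target_hu` must be strictly positive.",
      class = "contrastflow_validation_error")
  }
  idr_expected <- anchor$flow_ml_s * agent$iodine_mg_ml / 1000
  if (abs(anchor$idr_gi_s - idr_expected) > 1e-6) {
    abort(sprintf(
      "Inconsistent anchor: idr_gi_s = %.4f but flow * Ic/1000 = %.4f.",
      anchor$idr_gi_s, idr_expected
    ), class = "contrastflow_validation_error")
  }
  bv <- nadler_bv(anchor$sex, anchor$height_m, anchor$weight_kg)
  k <- anchor$target_hu * anchor$kv * bv /
    (anchor$flow_ml_s * agent$iodine_mg_ml)
  c_cal <- anchor$flow_ml_s / (bv * anchor$kv)
  if (flow_constant == "legacy") {
    warn(paste0(
      "Using the legacy literal flow constant 2e-4; it does not ",
      "reproduce the reference-anchor flow rate."
    ))
    c_cal <- 2e-4
  }
  structure(list(
    k = k, c_cal = c_cal,
    anchor = c(anchor, list(bv_l = bv)),
    agent = agent, flow_constant = flow_constant
  ), class = "cm_calibration")
}

#' @export
print.cm_calibration <- function(x, ...) {
  cat("<cm_calibration>\n")
  cat(sprintf("  anchor: %s, %.2f m, %.0f kg (BV %.3f L), %g kV, %g mL/s -> %g HU\n",
    x$anchor$sex, x$anchor$height_m, x$anchor$weight_kg, x$anchor$bv_l,
    x$anchor$kv, x$anchor$flow_ml_s, x$anchor$target_hu))
  cat(sprintf("  agent:  %s, %g mgI/mL\n", x$agent$name, x$agent$iodine_mg_ml))
  cat(sprintf("  k = %.4f, c_cal = %.6f (%s)\n", x$k, x$c_cal,
    x$flow_constant))
  invisible(x)
}

#' @rdname calibrate_attenuation
#' @param x A `cm_calibration` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cm_calibration <- function(x, ...) {
  tibble(
    term = c("k", "c_cal"),
    estimate = c(x$k, x$c_cal),
    unit = c("HU per (mgI/mL / kV / L)", "mL s^-1 L^-1 kV^-1")
  )
}

#' @rdname calibrate_attenuation
#' @exportS3Method generics::glance
glance.cm_calibration <- function(x, ...) {
  tibble(
    k = x$k, c_cal = x$c_cal, flow_constant = x$flow_constant,
    anchor_bv_l = x$anchor$bv_l, anchor_kv = x$anchor$kv,
    anchor_flow_ml_s = x$anchor$flow_ml_s,
    anchor_target_hu = x$anchor$target_hu,
    iodine_mg_ml = x$agent$iodine_mg_ml
  )
}

# Tube voltages offered by the voltage-selection steps.
.kv_whitelist <- c(70, 80, 90, 100, 110, 120)

#' Personalised flow rate
#'
#' `F = c_cal * BV * kV`, rounded to injector granularity (0.1 mL/s) by
#' default; strictly increasing in blood volume and tube voltage.
#'
#' @param bv_l Blood volume in litres (vectorised).
#' @param kv Tube voltage in kV; must be one of 70/80/90/100/110/120
#'   unless `allow_any_kv = TRUE` (manual overrides, e.g. pacemaker
#'   patients fixed at 120 kV, are on the whitelist already).
#' @param cal A `cm_calibration`.
#' @param round Round to 0.1 mL/s (default `TRUE`).
#' @param allow_any_kv Permit off-whitelist voltages.
#' @return Flow rate in mL/s.
#' @export
#' @examples
#' cal <- calibrate_attenuation()
#' flow_rate(5.319, 120, cal) # 7.0
flow_rate <- function(bv_l, kv, cal, round = TRUE, allow_any_kv = FALSE) {
  stopifnot(inherits(cal, "cm_calibration"))
  if (any(bv_l <= 0 | bv_l >= 12)) {
    abort("Field `bv_l` must lie in (0, 12) litres.",
      class = "contrastflow_validation_error")
  }
  if (!allow_any_kv && !all(kv %in% .kv_whitelist)) {
    abort(paste0(
      "Field `kv` must be one of ", paste(.kv_whitelist, collapse = "/"),
      " (set allow_any_kv = TRUE to override)."
    ), class = "contrastflow_validation_error")
  }
  f <- cal$c_cal * bv_l * kv
  if (round) round(f, 1) else f
}

#' Predicted intravascular attenuation
#'
#' `HU = k * F * Ic / (kV * BV)`: linear in flow, inversely proportional
#' to tube voltage and blood volume. At the personalised flow from
#' [flow_rate()] (pre-rounding) this returns the anchor's target
#' attenuation for every patient.
#'
#' @param flow_ml_s Flow rate, mL/s.
#' @param kv Tube voltage, kV.
#' @param bv_l Blood volume, litres.
#' @param cal A `cm_calibration`.
#' @return Predicted attenuation in HU.
#' @export
#' @examples
#' cal <- calibrate_attenuation()
#' predicted_attenuation(7.0, 120, 5.319, cal) # ~350
predicted_attenuation <- function(flow_ml_s, kv, bv_l, cal) {
  if (!inherits(cal, "cm_calibration")) {
    abort("Calibration required: pass a `cm_calibration` object.",
      class = "contrastflow_calibration_error")
  }
  if (any(kv <= 0) || any(bv_l <= 0)) {
    abort("`kv` and `bv_l` must be strictly positive.",
      class = "contrastflow_validation_error")
  }
  cal$k * flow_ml_s * cal$agent$iodine_mg_ml / (kv * bv_l)
}
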