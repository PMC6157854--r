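# Synthetic cohort generation and tube-voltage-selection emulation.
#
# Defaults emulate a 114-patient clinical CCTA population: 55 men and 59
# women, pooled height 1.71 +/- 0.10 m, weight 77.5 +/- 16.0 kg, heart
# rate 64.1 +/- 11.2 bpm truncated to [40, 90] (faster hearts get the
# out-of-scope helical protocol). The pooled marginals are reached with
# sex-specific bivariate normals: men 1.78 +/- 0.07 m and 85 +/- 14 kg,
# women 1.65 +/- 0.07 m and 70 +/- 13 kg, height-weight correlation 0.5.

#' Cohort configuration
#'
#' @param n_male,n_female Group sizes (default 55/59).
#' @param male_height,female_height `c(mean, sd)` in metres.
#' @param male_weight,female_weight `c(mean, sd)` in kilograms.
#' @param hw_correlation Height-weight correlation, in (-1, 1).
#' @param hr Heart-rate `c(mean, sd)` in bpm.
#' @param hr_bounds Truncation bounds for heart rate, bpm.
#' @param pacemaker_rate Probability of a pacemaker flag (default 0).
#' @param seed Optional default seed for [sample_cohort()].
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_male = 55, n_female = 59,
                          male_height = c(1.78, 0.07),
                          male_weight = c(85, 14),
                          female_height = c(1.65, 0.07),
                          female_weight = c(70, 13),
                          hw_correlation = 0.5,
                          hr = c(64.1, 11.2),
                          hr_bounds = c(40, 90),
                          pacemaker_rate = 0,
                          seed = NULL) {
  cfg <- list(n_male = n_male, n_female = n_female,
    male_height = male_height, male_weight = male_weight,
    female_height = female_height, female_weight = female_weight,
    hw_correlation = hw_correlation, hr = hr, hr_bounds = hr_bounds,
    pacemaker_rate = pacemaker_rate, seed = seed)
  sds <- c(male_height[2], male_weight[2], female_height[2],
    female_weight[2], hr[2])
  if (any(sds <= 0)) {
    abort("All standard deviations must be strictly positive.",
      class = "contrastflow_validation_error")
  }
  if (abs(hw_correlation) >= 1) {
    abort("Field `hw_correlation` must lie in (-1, 1).",
      class = "contrastflow_validation_error")
  }
  if (n_male < 0 || n_female < 0) {
    abort("Group sizes must be non-negative.",
      class = "contrastflow_validation_error")
  }
  structure(cfg, class = "cohort_config")
}

# inverse-CDF sampler for a truncated normal; errors when the bounds
# exclude more than 99% of the mass (infeasible truncation)
rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  if (p_hi - p_lo < 0.01) {
    abort(sprintf(
      "Infeasible truncation [%g, %g]: bounds retain %.2f%% of the mass.",
      lower, upper, 100 * (p_hi - p_lo)
    ), class = "contrastflow_validation_error")
  }
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

sample_sex_block <- function(n, sex, height, weight, rho) {
  if (n == 0) {
    return(tibble(sex = character(), height_m = double(),
      weight_kg = double()))
  }
  sigma <- matrix(c(
    height[2]^2, rho * height[2] * weight[2],
    rho * height[2] * weight[2], weight[2]^2
  ), 2)
  draw <- function(m) MASS::mvrnorm(m, c(height[1], weight[1]), sigma)
  x <- draw(n)
  # redraw the rare samples outside patient validity
  bad <- x[, 1] <= 0.5 | x[, 1] >= 2.5 | x[, 2] <= 20 | x[, 2] >= 250
  guard <- 0
  while (any(bad)) {
    x[bad, ] <- draw(sum(bad))
    bad <- x[, 1] <= 0.5 | x[, 1] >= 2.5 | x[, 2] <= 20 | x[, 2] >= 250
    guard <- guard + 1
    if (guard > 100) {
      abort("Anthropometric configuration places most mass outside patient validity.",
        class = "contrastflow_validation_error")
    }
  }
  tibble(sex = rep(sex, n), height_m = x[, 1], weight_kg = x[, 2])
}

#' Sample a synthetic patient cohort
#'
#' Per sex, (height, weight) are drawn from a bivariate normal with the
#' configured marginals and correlation (redrawing the negligible mass
#' outside patient validity); heart rate from a truncated normal.
#' Fully reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @return A patient tibble (`id, sex, height_m, weight_kg,
#'   heart_rate_bpm, pacemaker`).
#' @export
#' @examples
#' sample_cohort(cohort_config(n_male = 2, n_female = 2), seed = 1)
sample_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) withr::local_seed(seed)
  men <- sample_sex_block(config$n_male, "male", config$male_height,
    config$male_weight, config$hw_correlation)
  women <- sample_sex_block(config$n_female, "female",
    config$female_height, config$female_weight, config$hw_correlation)
  cohort <- bind_rows(men, women)
  n <- nrow(cohort)
  cohort$heart_rate_bpm <- rtruncnorm_icdf(n, config$hr[1], config$hr[2],
    config$hr_bounds[1], config$hr_bounds[2])
  cohort$pacemaker <- runif(n) < config$pacemaker_rate
  cohort$id <- sprintf("S%05d", seq_len(n))
  validate_patients(cohort)
}

#' Tube-voltage-selection emulator with fixed thresholds
#'
#' A piecewise-constant, monotone non-decreasing map from blood volume to
#' tube voltage: blood volumes up to the first threshold get the lowest
#' kV, and so on. This emulates the *outcome distribution* of automated
#' tube voltage selection using blood volume as the body-size proxy; it
#' does not replicate any vendor algorithm.
#'
#' @param kv_levels Ordered tube voltages (default 70/80/90 kV).
#' @param bv_thresholds Strictly increasing thresholds in litres, one
#'   fewer than `kv_levels`.
#' @return An `atvs_emulator` object.
#' @export
atvs_emulator <- function(kv_levels = c(70, 80, 90), bv_thresholds) {
  if (length(bv_thresholds) != length(kv_levels) - 1) {
    abort("`bv_thresholds` must have one fewer element than `kv_levels`.",
      class = "contrastflow_validation_error")
  }
  if (is.unsorted(bv_thresholds, strictly = TRUE)) {
    abort("`bv_thresholds` must be strictly increasing.",
      class = "contrastflow_validation_error")
  }
  structure(list(kv_levels = kv_levels,
    bv_thresholds = as.numeric(bv_thresholds)), class = "atvs_emulator")
}

#' Build an emulator from a cohort's blood volumes
#'
#' Places the thresholds at the blood-volume quantiles corresponding to
#' the target cumulative kV shares (defaults: 52.6% at the lowest kV and
#' 85.1% at or below the middle kV, i.e. shares 52.6/32.5/14.9%).
#'
#' @param bv_l Blood volumes of the cohort, litres.
#' @param cum_shares Cumulative shares at the lower kV levels.
#' @param kv_levels Ordered tube voltages.
#' @return An [atvs_emulator()].
#' @export
atvs_from_cohort <- function(bv_l, cum_shares = c(0.526, 0.851),
                             kv_levels = c(70, 80, 90)) {
  atvs_emulator(kv_levels, quantile(bv_l, cum_shares, names = FALSE))
}

#' Emulate tube-voltage selection
#'
#' @param bv_l Blood volumes in litres, each in (0, 12).
#' @param emu An [atvs_emulator()].
#' @return Tube voltages (kV), monotone non-decreasing in `bv_l`.
#' @export
emulate_atvs <- function(bv_l, emu) {
  stopifnot(inherits(emu, "atvs_emulator"))
  if (any(bv_l <= 0 | bv_l >= 12)) {
    abort("Field `bv_l` must lie in (0, 12) litres.",
      class = "contrastflow_validation_error")
  }
  emu$kv_levels[findInterval(bv_l, emu$bv_thresholds,
    left.open = TRUE) + 1L]
}

#' Assign tube voltages to a cohort by quantile thresholds
#'
#' Default path used by [simulate_study()]: thresholds are placed at the
#' configured quantiles of the blood-volume distribution *within each
#' sex* (`stratify_by_sex = TRUE`), which preserves the target kV shares
#' exactly overall and per sex; `stratify_by_sex = FALSE` uses pooled
#' cohort quantiles.
#'
#' @param bv_l Blood volumes, litres.
#' @param sex Sex vector (required when stratifying).
#' @param cum_shares,kv_levels See [atvs_from_cohort()].
#' @param stratify_by_sex Stratify thresholds by sex (default `TRUE`).
#' @return Tube voltages (kV).
#' @export
assign_kv <- function(bv_l, sex = NULL, cum_shares = c(0.526, 0.851),
                      kv_levels = c(70, 80, 90),
                      stratify_by_sex = TRUE) {
  if (!stratify_by_sex || is.null(sex)) {
    return(emulate_atvs(bv_l, atvs_from_cohort(bv_l, cum_shares, kv_levels)))
  }
  sex <- normalize_sex(sex)
  kv <- numeric(length(bv_l))
  for (s in unique(sex)) {
    i <- sex == s
    kv[i] <- emulate_atvs(bv_l[i],
      atvs_from_cohort(bv_l[i], cum_shares, kv_levels))
  }
  kv
}

#' Simulate a full protocol study
#'
#' End-to-end driver: sample a cohort, compute blood volumes, emulate
#' tube-voltage selection, assign scan modes from heart rate, and
#' generate the personalised injection protocol for every synthetic
#' patient. Pacemaker patients (if configured) are fixed at 120 kV.
#'
#' @param config A [cohort_config()].
#' @param cal A [calibrate_attenuation()] result.
#' @param seed Integer seed for reproducibility.
#' @param emu Optional fixed [atvs_emulator()]; default uses sex-
#'   stratified quantile thresholds via [assign_kv()].
#' @param stratify_atvs Stratify quantile thresholds by sex (default
#'   `TRUE`; ignored when `emu` is given).
#' @param ... Passed to [generate_protocol()] (e.g. `test_bolus_s`).
#' @return A `cm_study` object: list with `patients`, `protocols`
#'   (tibbles), `characteristics` (summary tibble), `config` and `cal`.
#' @export
#' @examples
#' study <- simulate_study(seed = 42)
#' glance(study)
simulate_study <- function(config = cohort_config(),
                           cal = calibrate_attenuation(),
                           seed = NULL, emu = NULL,
                           stratify_atvs = TRUE, ...) {
  if (!is.null(seed)) withr::local_seed(seed)
  patients <- sample_cohort(config)
  patients <- add_blood_volume(patients)
  if (is.null(emu)) {
    patients$kv <- assign_kv(patients$bv_l, patients$sex,
      stratify_by_sex = stratify_atvs)
  } else {
    patients$kv <- emulate_atvs(patients$bv_l, emu)
  }
  patients$kv[patients$pacemaker] <- 120
  patients$mode <- assign_scan_mode(patients$heart_rate_bpm)
  protocols <- generate_protocol(patients, cal, ...)
  structure(list(
    patients = patients,
    protocols = protocols,
    characteristics = cohort_characteristics(patients),
    config = config, cal = cal
  ), class = "cm_study")
}

#' Cohort characteristics summary
#'
#' Mean and SD of height, weight, BMI, blood volume (overall and per
#' sex) and heart rate, plus scan-mode and kV counts when present.
#'
#' @param patients Patient tibble (blood volume added if absent).
#' @return A tibble with columns `characteristic, group, n, mean, sd`.
#' @export
cohort_characteristics <- function(patients) {
  if (!"bv_l" %in% names(patients)) patients <- add_blood_volume(patients)
  patients <- add_bmi(patients)
  num <- function(x, ch, group) {
    tibble(characteristic = ch, group = group, n = sum(!is.na(x)),
      mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  }
  out <- bind_rows(
    num(patients$height_m, "height_m", "overall"),
    num(patients$weight_kg, "weight_kg", "overall"),
    num(patients$bmi_kg_m2, "bmi_kg_m2", "overall"),
    num(patients$bv_l, "bv_l", "overall"),
    num(patients$bv_l[patients$sex == "male"], "bv_l", "male"),
    num(patients$bv_l[patients$sex == "female"], "bv_l", "female"),
    num(patients$heart_rate_bpm, "heart_rate_bpm", "overall")
  )
  for (col in c("mode", "kv")) {
    if (col %in% names(patients)) {
      tab <- table(patients[[col]])
      out <- bind_rows(out, tibble(
        characteristic = paste0("n_", col, "_", names(tab)),
        group = "overall", n = as.integer(tab),
        mean = NA_real_, sd = NA_real_
      ))
    }
  }
  out
}

#' @export
print.cm_study <- function(x, ...) {
  cat(sprintf("<cm_study> %d synthetic patients\n", nrow(x$patients)))
  print(glance(x))
  invisible(x)
}

#' @rdname simulate_study
#' @param x A `cm_study` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cm_study <- function(x, ...) protocol_table(x$protocols)

#' @rdname simulate_study
#' @exportS3Method generics::glance
glance.cm_study <- function(x, ...) {
  p <- x$patients
  tibble(
    n = nrow(p),
    n_male = sum(p$sex == "male"),
    mean_height_m = mean(p$height_m),
    mean_weight_kg = mean(p$weight_kg),
    mean_bv_l = mean(p$bv_l),
    mean_hr_bpm = mean(p$heart_rate_bpm),
    pct_high_pitch = 100 * mean(p$mode == "high_pitch"),
    pct_70kv = 100 * mean(p$kv == 70),
    pct_80kv = 100 * mean(p$kv == 80),
    pct_90kv = 100 * mean(p$kv == 90),
    mean_flow_ml_s = mean(x$protocols$flow_ml_s),
    mean_main_bolus_ml = mean(x$protocols$main_bolus_ml)
  )
}
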