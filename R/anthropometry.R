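# Patient anthropometrics and Nadler blood-volume estimation.
#
# Validation ranges are deliberately generous screens against data-entry
# errors, not physiological reference intervals: height (0.5, 2.5) m,
# weight (20, 250) kg, heart rate (30, 220) bpm.

.height_range <- c(0.5, 2.5)
.weight_range <- c(20, 250)
.hr_range <- c(30, 220)

#' Normalise a sex encoding
#'
#' Accepts `"male"`/`"female"`, `"M"`/`"F"` (any case) and returns a
#' character vector with levels `"male"` and `"female"`.
#'
#' @param sex Character vector.
#' @return Character vector of `"male"`/`"female"`.
#' @export
normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("m", "male"), "male",
    ifelse(s %in% c("f", "female"), "female", NA_character_)
  )
  if (anyNA(out)) {
    bad <- unique(sex[is.na(out)])
    abort(paste0(
      "Field `sex` must be 'male'/'female' (or 'M'/'F'); got: ",
      paste(bad, collapse = ", ")
    ), class = "contrastflow_validation_error")
  }
  out
}

check_range <- function(x, range, field, allow_na = FALSE) {
  bad <- !is.na(x) & (x <= range[1] | x >= range[2])
  if (!allow_na && anyNA(x)) {
    abort(paste0("Field `", field, "` contains missing values."),
      class = "contrastflow_validation_error")
  }
  if (any(bad)) {
    abort(sprintf(
      "Field `%s` out of range (%g, %g): offending value(s) %s",
      field, range[1], range[2],
      paste(utils::head(unique(x[bad]), 3L), collapse = ", ")
    ), class = "contrastflow_validation_error")
  }
  invisible(x)
}

#' Validate a patient table
#'
#' Checks the canonical patient columns: `sex` (male/female or M/F),
#' `height_m` in (0.5, 2.5), `weight_kg` in (20, 250) and, when present,
#' `heart_rate_bpm` in (30, 220) (missing heart rates are allowed). Heights
#' above 3 are interpreted as centimetres and converted to metres, so
#' operator-entered `178` and `1.78` denote the same patient.
#'
#' @param patients Data frame with at least `sex`, `height_m`, `weight_kg`.
#' @return The validated table as a tibble, sex normalised, heights in
#'   metres, with a logical `pacemaker` column (default `FALSE`).
#' @export
#' @examples
#' validate_patients(data.frame(sex = "M", height_m = 178, weight_kg = 80))
validate_patients <- function(patients) {
  patients <- as_tibble(patients)
  for (col in c("sex", "height_m", "weight_kg")) {
    if (!col %in% names(patients)) {
      abort(paste0("Field `", col, "` is missing from the patient table."),
        class = "contrastflow_validation_error")
    }
  }
  patients$sex <- normalize_sex(patients$sex)
  patients$height_m <- ifelse(patients$height_m > 3,
    patients$height_m / 100, patients$height_m)
  check_range(patients$height_m, .height_range, "height_m")
  check_range(patients$weight_kg, .weight_range, "weight_kg")
  if ("heart_rate_bpm" %in% names(patients)) {
    check_range(patients$heart_rate_bpm, .hr_range, "heart_rate_bpm",
      allow_na = TRUE)
  }
  if (!"pacemaker" %in% names(patients)) patients$pacemaker <- FALSE
  patients$pacemaker <- isTRUE_vec(patients$pacemaker)
  if (!"id" %in% names(patients)) {
    patients$id <- sprintf("P%03d", seq_len(nrow(patients)))
  }
  select(patients, "id", "sex", "height_m", "weight_kg",
    dplyr::any_of(c("heart_rate_bpm", "pacemaker")),
    dplyr::everything())
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Nadler blood volume
#'
#' Sex-specific total blood volume (litres) from height and weight:
#' males `0.3669 h^3 + 0.03219 w + 0.6041`, females
#' `0.3561 h^3 + 0.03308 w + 0.1833`, with height `h` in metres and
#' weight `w` in kilograms.
#'
#' @param sex Character vector, `"male"`/`"female"` (or M/F).
#' @param height_m Height in metres.
#' @param weight_kg Weight in kilograms.
#' @param validate Apply the patient range checks (default `TRUE`). Set to
#'   `FALSE` to evaluate the bare formula, e.g. at its intercept.
#' @return Numeric vector of blood volumes in litres.
#' @export
#' @examples
#' nadler_bv("male", 1.80, 80) # 5.319 L
#' nadler_bv("female", 1.65, 60) # 3.768 L
nadler_bv <- function(sex, height_m, weight_kg, validate = TRUE) {
  sex <- normalize_sex(sex)
  if (validate) {
    check_range(height_m, .height_range, "height_m")
    check_range(weight_kg, .weight_range, "weight_kg")
  }
  n <- max(length(sex), length(height_m), length(weight_kg))
  sex <- rep_len(sex, n)
  height_m <- rep_len(height_m, n)
  weight_kg <- rep_len(weight_kg, n)
  ifelse(sex == "male",
    0.3669 * height_m^3 + 0.03219 * weight_kg + 0.6041,
    0.3561 * height_m^3 + 0.03308 * weight_kg + 0.1833
  )
}

#' Add Nadler blood volume to a patient table
#'
#' @param patients Patient table (see [validate_patients()]).
#' @return The table with columns `bv_l` (litres) and `bv_formula`
#'   (`"nadler_male"`/`"nadler_female"`) appended.
#' @export
#' @examples
#' add_blood_volume(data.frame(sex = c("M", "F"),
#'   height_m = c(1.80, 1.65), weight_kg = c(80, 60)))
add_blood_volume <- function(patients) {
  patients <- validate_patients(patients)
  mutate(patients,
    bv_l = nadler_bv(.data$sex, .data$height_m, .data$weight_kg,
      validate = FALSE),
    bv_formula = paste0("nadler_", .data$sex)
  )
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Height in metres (must be positive).
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(80, 1.80)
bmi <- function(weight_kg, height_m) {
  if (any(!is.na(height_m) & height_m <= 0)) {
    abort("Field `height_m` must be positive for BMI.",
      class = "contrastflow_validation_error")
  }
  weight_kg / height_m^2
}

#' Add BMI to a patient table
#'
#' @inheritParams add_blood_volume
#' @return The table with a `bmi_kg_m2` column appended.
#' @export
add_bmi <- function(patients) {
  patients <- validate_patients(patients)
  mutate(patients, bmi_kg_m2 = bmi(.data$weight_kg, .data$height_m))
}

#' Read a patient CSV
#'
#' Expected columns: `id,sex,height_m,weight_kg,heart_rate_bpm,pacemaker`
#' (header required; sex M/F; empty heart rate allowed; UTF-8, comma
#' separated, "." decimal).
#'
#' @param path Path to the CSV file.
#' @return Validated patient tibble.
#' @export
read_patients <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    sex = readr::col_character(),
    height_m = readr::col_double(),
    weight_kg = readr::col_double(),
    heart_rate_bpm = readr::col_double(),
    pacemaker = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  validate_patients(raw)
}
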