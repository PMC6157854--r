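# YAML configuration support for the command-line scripts.

#' Build a calibration from a configuration list or YAML file
#'
#' Recognised structure:
#' ```yaml
#' anchor: {height_m: 1.80, weight_kg: 80, sex: male, kv: 120,
#'          flow_ml_s: 7.0, target_hu: 350}
#' agent: {name: iopromide, iodine_mg_ml: 300}
#' flow_constant: anchor        # or "legacy"
#' ```
#' Missing blocks fall back to the defaults; the anchor IDR is derived
#' from its flow and the agent concentration.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @return A `cm_calibration`.
#' @export
calibration_from_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  agent_cfg <- config$agent %||% list()
  agent <- contrast_agent(
    name = agent_cfg$name %||% "iopromide",
    iodine_mg_ml = agent_cfg$iodine_mg_ml %||% 300
  )
  a <- config$anchor %||% list()
  flow <- a$flow_ml_s %||% 7.0
  anchor <- reference_anchor(
    height_m = a$height_m %||% 1.80,
    weight_kg = a$weight_kg %||% 80,
    sex = a$sex %||% "male",
    kv = a$kv %||% 120,
    flow_ml_s = flow,
    target_hu = a$target_hu %||% 350,
    idr_gi_s = flow * agent$iodine_mg_ml / 1000
  )
  calibrate_attenuation(anchor, agent,
    flow_constant = config$flow_constant %||% "anchor")
}

#' Build a cohort configuration from a list or YAML file
#'
#' Field names mirror [cohort_config()]; two-element fields are given as
#' YAML lists, e.g. `male_height: [1.78, 0.07]`.
#'
#' @param config Path to a YAML file, or a list.
#' @return A [cohort_config()].
#' @export
cohort_config_from_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config$cohort %||% config
  defaults <- cohort_config()
  args <- defaults[setdiff(names(unclass(defaults)), "seed")]
  for (nm in names(args)) {
    if (!is.null(config[[nm]])) args[[nm]] <- unlist(config[[nm]])
  }
  args$seed <- config$seed
  do.call(cohort_config, args)
}
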