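#' Load the run configuration
#'
#' Reads the packaged defaults (every policy constant, unit cost and assumed
#' synthetic parameter, the latter labeled `assumed: true`) and, when a path
#' is given, recursively merges the user's YAML overrides on top.
#'
#' @param path optional path to a YAML file overriding any subset of keys.
#' @return nested configuration list of class `run_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- yaml::read_yaml(system.file("extdata", "defaults.yaml",
                                     package = "donorecall", mustWork = TRUE))
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  for (s in c("female", "male")) {
    b <- cfg$behavior[[s]]
    check_prob(c(b$dropout_prob, b$other_deferral_prob),
               sprintf("behavior$%s probabilities", s))
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_config
#' @export
default_config <- function() read_config(NULL)

strip_assumed <- function(x) x[setdiff(names(x), "assumed")]

#' Build component objects from a configuration
#'
#' Constructors mapping `run_config` sections to the package's parameter
#' objects.
#'
#' @param cfg a [read_config()] list.
#' @param sex `"female"` or `"male"` for the sex-stratified pieces.
#' @param name strategy name for [config_strategy()].
#' @param n override for the population size.
#' @return the corresponding parameter object.
#' @export
config_population <- function(cfg, n = NULL) {
  p <- cfg$population
  population_config(
    n = n %||% p$n_donors,
    sex_mix = unlist(p$sex_mix),
    index_hb = list(female = unlist(strip_assumed(p$index_hb)$female),
                    male = unlist(strip_assumed(p$index_hb)$male)),
    index_hb_floor = p$index_hb_floor,
    age_mean = p$age$mean, age_sd = p$age$sd,
    age_range = c(p$age$min, p$age$max),
    ethnicity_freq = unlist(strip_assumed(p$ethnicity_freq)),
    blood_group_freq = unlist(strip_assumed(p$blood_group_freq)),
    latent_sd = cfg$model[[ "female" ]]$latent_sd)
}

#' @rdname config_population
#' @export
config_model <- function(cfg, sex) {
  m <- cfg$model[[sex]]
  recovery_model(sex = sex, intercept = m$intercept,
                 coef_index_hb = m$coef_index_hb, slope = m$slope,
                 age_coef = m$age_coef, age_ref = m$age_ref,
                 ethnicity_effects = unlist(cfg$model$ethnicity_effects),
                 blood_group_effects = unlist(cfg$model$blood_group_effects),
                 latent_sd = m$latent_sd, residual_sd = m$residual_sd,
                 se = cfg$model$se)
}

#' @rdname config_population
#' @export
config_behavior <- function(cfg, sex) {
  b <- cfg$behavior
  behavior_params(sex = sex,
                  dropout_prob = b[[sex]]$dropout_prob,
                  other_deferral_prob = b[[sex]]$other_deferral_prob,
                  delay_mean_weeks = b$delay$mean_weeks,
                  delay_cap_weeks = b$delay$cap_weeks,
                  onsite_error = strip_assumed(b$onsite_error),
                  hemocue_over_prob = b$hemocue_over_prob)
}

#' @rdname config_population
#' @export
config_thresholds <- function(cfg, sex) {
  t <- cfg$thresholds[[sex]]
  threshold_spec(sex, donation_threshold = t$donation,
                 severe_low = t$severe_low)
}

#' @rdname config_population
#' @export
config_rules <- function(cfg) {
  d <- cfg$deferral
  deferral_rules(d$low_hb_weeks, d$low_hb_severe_weeks, d$other_weeks)
}

#' @rdname config_population
#' @export
config_costs <- function(cfg) {
  k <- cfg$costs
  cost_table(k$onsite_test, k$offsite_test, k$donation, k$deferral_low_hb,
             k$deferral_other)
}

#' @rdname config_population
#' @export
config_strategy <- function(cfg, name) {
  caps <- cfg$strategies$max_invitations_per_year
  make_strategy(name,
                max_invitations_per_year =
                  if (name == "A") caps$A else caps$personalized,
                interval_cap = cfg$strategies$interval_cap_weeks)
}
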