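.BOOT_OUTCOMES <- c("donations", "donations_under", "low_hb_deferrals",
                    "other_deferrals", "lapses", "adverse_events",
                    "donations_per_adverse_event", "mean_cost_per_donation",
                    "total_cost_gbp")

# Draw one perturbed copy of a recovery model: normal on coefficients,
# log-normal on the variance-component sds. Uses the current RNG stream.
perturb_model <- function(model) {
  se <- model$se
  m <- model
  draw <- function(est, s) if (is.null(s) || is.na(s) || s == 0) est
                           else stats::rnorm(1, est, s)
  m$intercept <- draw(model$intercept, se$intercept)
  m$coef_index_hb <- draw(model$coef_index_hb, se$coef_index_hb)
  m$slope <- draw(model$slope, se$slope)
  m$age_coef <- draw(model$age_coef, se$age_coef)
  ln_draw <- function(est, s) {
    if (est <= 0 || is.null(s) || is.na(s) || s == 0) return(est)
    est * exp(stats::rnorm(1, 0, s / est))   # cv-parameterized log-normal
  }
  m$latent_sd <- ln_draw(model$latent_sd, se$latent_sd)
  m$residual_sd <- ln_draw(model$residual_sd, se$residual_sd)
  m
}

# Logit-normal perturbation of the behavioral probabilities. Default SEs are
# binomial standard errors at the calibration denominators.
perturb_behavior <- function(behavior, se = NULL) {
  se <- se %||% list(
    dropout_prob = sqrt(behavior$dropout_prob *
                          (1 - behavior$dropout_prob) / 1000),
    other_deferral_prob = sqrt(behavior$other_deferral_prob *
                                 (1 - behavior$other_deferral_prob) / 900))
  b <- behavior
  logit_draw <- function(p, s) {
    if (p <= 0 || p >= 1 || is.null(s) || is.na(s) || s == 0) return(p)
    s_logit <- s / (p * (1 - p))
    stats::plogis(stats::rnorm(1, stats::qlogis(p), s_logit))
  }
  b$dropout_prob <- logit_draw(behavior$dropout_prob, se$dropout_prob)
  b$other_deferral_prob <- logit_draw(behavior$other_deferral_prob,
                                      se$other_deferral_prob)
  b
}

#' Bootstrap uncertainty intervals for simulation outcomes
#'
#' Propagates parameter uncertainty through the simulation: for each draw the
#' data-informed parameters are perturbed from their joint sampling
#' distribution (normal on regression coefficients, log-normal on variance
#' component sds, logit-normal on behavioral probabilities), a cohort of
#' `size` donors is resampled from the reference population and simulated,
#' and the per-1000 outcomes are recorded. Point estimates are medians across
#' draws, with 2.5th/97.5th percentile uncertainty intervals. The reported
#' design uses 1000 draws of 1000 individuals.
#'
#' @inheritParams run_population
#' @param reference reference `donor_population` (single sex) to resample.
#' @param draws number of bootstrap parameter draws.
#' @param size donors per draw.
#' @param behavior_se optional list of SEs for the behavioral probabilities;
#'   defaults to binomial standard errors.
#' @param scale_to report counts per this many donors.
#' @return an `uncertainty_summary` data.frame with one row per outcome and
#'   columns `outcome`, `point` (median), `lower`, `upper`; the number of
#'   draws is attached as an attribute.
#' @export
bootstrap_uncertainty <- function(reference, strategy,
                                  model = default_recovery_model(reference$sex[1]),
                                  behavior = behavior_params(reference$sex[1]),
                                  rules = deferral_rules(),
                                  thresholds = threshold_spec(reference$sex[1]),
                                  draws = 1000, size = 1000, seed = 1,
                                  behavior_se = NULL, scale_to = 1000) {
  if (nrow(reference) == 0L) stopf("reference population is empty")
  fixed <- is.null(model$se)
  if (fixed)
    warning("model carries no standard errors; bootstrapping with fixed ",
            "parameters (Monte-Carlo variation only)", call. = FALSE)
  rs <- .restore_rng()
  on.exit(rs(), add = TRUE)
  draw_seeds <- donor_seeds(seed, 2L * draws)
  res <- matrix(NA_real_, nrow = draws, ncol = length(.BOOT_OUTCOMES),
                dimnames = list(NULL, .BOOT_OUTCOMES))
  lat0 <- model$latent_sd
  for (d in seq_len(draws)) {
    set.seed(draw_seeds[2L * d - 1L])
    m_d <- if (fixed) model else perturb_model(model)
    b_d <- if (fixed) behavior else perturb_behavior(behavior, behavior_se)
    cohort <- resample_population(reference, size,
                                  seed = draw_seeds[2L * d - 1L])
    if (!fixed && lat0 > 0 && m_d$latent_sd != lat0)
      cohort$latent_offset <- cohort$latent_offset * m_d$latent_sd / lat0
    log <- run_population(cohort, strategy, m_d, b_d, rules, thresholds,
                          seed = draw_seeds[2L * d])
    s <- summary(log, scale_to = scale_to)
    res[d, ] <- c(s$donations, s$counts[["donations_under"]],
                  s$counts[["low_hb_deferrals"]],
                  s$counts[["other_deferrals"]], s$counts[["lapses"]],
                  s$adverse_events, s$donations_per_adverse_event,
                  s$mean_cost_per_donation, s$total_cost_gbp)
  }
  qs <- apply(res, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  out <- data.frame(outcome = .BOOT_OUTCOMES, point = qs[1, ],
                    lower = qs[2, ], upper = qs[3, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, draws = draws, size = size, strategy = strategy$name,
            sex = reference$sex[1],
            class = c("uncertainty_summary", "data.frame"))
}

#' @export
#' @method print uncertainty_summary
print.uncertainty_summary <- function(x, ...) {
  cat(sprintf("Bootstrap uncertainty: strategy %s, %s, %d draws of %d donors\n",
              attr(x, "strategy"), attr(x, "sex"), attr(x, "draws"),
              attr(x, "size")))
  df <- as.data.frame(x)
  df$point <- sprintf("%.2f", df$point)
  df$`95% UI` <- sprintf("(%.2f, %.2f)", df$lower, df$upper)
  print(df[c("outcome", "point", "95% UI")], row.names = FALSE)
  invisible(x)
}
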