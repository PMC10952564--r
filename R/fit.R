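#' Fit a hemoglobin recovery model to longitudinal donor data
#'
#' Estimates the sex-stratified linear recovery model from a table of return
#' hemoglobin measurements. Two designs are supported:
#'
#' * single return per donor (one row per `id`): ordinary least squares with
#'   the index hemoglobin as a fixed covariate. The between-donor and
#'   within-donor variance components are not separately identifiable from one
#'   return, so the fit reports the total predictive sd as `residual_sd` with
#'   `latent_sd = 0` — marginal predictions (and hence recall policies) are
#'   unchanged by this convention.
#' * repeated returns per donor (duplicated `id`): a linear mixed model with a
#'   donor random intercept via [lme4::lmer()] (REML), which separates
#'   `latent_sd` from `residual_sd`.
#'
#' @param data data.frame with columns `id`, `sex` (single stratum), `age`,
#'   `ethnicity`, `blood_group`, `index_hb`, `t_weeks` (weeks since index
#'   donation) and `return_hb` (g/L).
#' @param method `"auto"` (mixed model iff `id` is duplicated), `"lm"` or
#'   `"lmer"`.
#' @param age_ref centering age in years for the intercept parameterization.
#' @param ref_ethnicity,ref_blood_group reference categories (effect 0);
#'   defaults to `"White"` / `"O+"` when present.
#' @return an object of classes `recovery_fit` and `recovery_model`: usable
#'   everywhere a [recovery_model()] is, with `print`, `summary`, `coef`,
#'   `vcov` and `residuals` methods and standard errors for bootstrap
#'   perturbation in `$se`.
#' @examples
#' pop <- generate_reference_population(population_config(n = 500), seed = 2,
#'                                      sex = "female")
#' dat <- generate_two_visit_dataset(default_recovery_model("female"), pop,
#'                                   return_times = 10 + (seq_len(500) %% 15),
#'                                   seed = 3)
#' fit <- fit_recovery_model(dat)
#' coef(fit)["slope"]
#' @export
fit_recovery_model <- function(data, method = c("auto", "lm", "lmer"),
                               age_ref = 45,
                               ref_ethnicity = NULL, ref_blood_group = NULL) {
  method <- match.arg(method)
  need <- c("id", "sex", "age", "ethnicity", "blood_group", "index_hb",
            "t_weeks", "return_hb")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("data lacks columns: %s", paste(miss, collapse = ", "))
  sexes <- unique(data$sex)
  if (length(sexes) != 1L)
    stopf("fit one sex stratum at a time (found: %s)",
          paste(sexes, collapse = ", "))
  if (method == "auto")
    method <- if (anyDuplicated(data$id)) "lmer" else "lm"

  d <- data
  d$age_c <- d$age - age_ref
  relevel_to <- function(x, ref, preferred) {
    x <- factor(x)
    ref <- ref %||% if (preferred %in% levels(x)) preferred else levels(x)[1]
    stats::relevel(x, ref = ref)
  }
  d$ethnicity <- relevel_to(d$ethnicity, ref_ethnicity, "White")
  d$blood_group <- relevel_to(d$blood_group, ref_blood_group, "O+")

  terms <- c("index_hb", "t_weeks", "age_c")
  if (nlevels(d$ethnicity) > 1) terms <- c(terms, "ethnicity")
  if (nlevels(d$blood_group) > 1) terms <- c(terms, "blood_group")
  rhs <- paste(terms, collapse = " + ")

  if (method == "lm") {
    fit <- stats::lm(stats::as.formula(paste("return_hb ~", rhs)), data = d)
    cf <- stats::coef(fit)
    if (anyNA(cf))
      stopf("design is rank deficient; collinear terms: %s",
            paste(names(cf)[is.na(cf)], collapse = ", "))
    sm <- summary(fit)
    ses <- sm$coefficients[, "Std. Error"]
    sigma <- sm$sigma
    latent_sd <- 0
    residual_sd <- sigma
    sigma_se <- sigma / sqrt(2 * fit$df.residual)
    vc <- stats::vcov(fit)
  } else {
    fit <- lme4::lmer(
      stats::as.formula(paste("return_hb ~", rhs, "+ (1 | id)")), data = d)
    cf <- lme4::fixef(fit)
    X <- lme4::getME(fit, "X")
    if (qr(X)$rank < ncol(X))
      stopf("design is rank deficient; check covariate coding")
    vc <- as.matrix(stats::vcov(fit))
    ses <- sqrt(diag(vc))
    names(ses) <- names(cf)
    vcs <- as.data.frame(lme4::VarCorr(fit))
    latent_sd <- vcs$sdcor[vcs$grp == "id"]
    residual_sd <- vcs$sdcor[vcs$grp == "Residual"]
    sigma_se <- NA_real_
  }

  pick <- function(v, nm, default = 0) if (nm %in% names(v)) v[[nm]] else default
  eff_vec <- function(src, fac, prefix) {
    out <- stats::setNames(numeric(nlevels(fac)), levels(fac))
    hit <- paste0(prefix, levels(fac))
    est <- src[intersect(hit, names(src))]
    out[sub(prefix, "", names(est), fixed = TRUE)] <- est
    out
  }

  model <- recovery_model(
    sex = sexes, intercept = unname(cf[["(Intercept)"]]),
    coef_index_hb = pick(cf, "index_hb"), slope = pick(cf, "t_weeks"),
    age_coef = pick(cf, "age_c"), age_ref = age_ref,
    ethnicity_effects = eff_vec(cf, d$ethnicity, "ethnicity"),
    blood_group_effects = eff_vec(cf, d$blood_group, "blood_group"),
    latent_sd = latent_sd, residual_sd = residual_sd,
    se = list(intercept = unname(ses[["(Intercept)"]]),
              coef_index_hb = pick(ses, "index_hb", NA_real_),
              slope = pick(ses, "t_weeks", NA_real_),
              age_coef = pick(ses, "age_c", NA_real_),
              ethnicity_effects = eff_vec(ses, d$ethnicity, "ethnicity"),
              blood_group_effects = eff_vec(ses, d$blood_group, "blood_group"),
              residual_sd = sigma_se, latent_sd = NA_real_))
  model$fit <- fit
  model$method <- method
  model$n_obs <- nrow(d)
  model$n_donors <- length(unique(d$id))
  model$vcov <- vc
  class(model) <- c("recovery_fit", "recovery_model")
  model
}

#' @export
coef.recovery_fit <- function(object, ...) {
  c(intercept = object$intercept, coef_index_hb = object$coef_index_hb,
    slope = object$slope, age_coef = object$age_coef,
    stats::setNames(object$ethnicity_effects,
                    paste0("ethnicity:", names(object$ethnicity_effects))),
    stats::setNames(object$blood_group_effects,
                    paste0("blood_group:", names(object$blood_group_effects))),
    latent_sd = object$latent_sd, residual_sd = object$residual_sd)
}

#' @export
vcov.recovery_fit <- function(object, ...) object$vcov

#' @export
residuals.recovery_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
#' @method print recovery_fit
print.recovery_fit <- function(x, ...) {
  cat(sprintf("Fitted hemoglobin recovery model (%s; %s on %d obs / %d donors)\n",
              x$sex, x$method, x$n_obs, x$n_donors))
  NextMethod()
}

#' @export
#' @method summary recovery_fit
summary.recovery_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' Predict mean hemoglobin or threshold-crossing probability
#'
#' @param object a [recovery_model()] or fitted `recovery_fit`.
#' @param newdata donor table (columns `age`, `ethnicity`, `blood_group`,
#'   `index_hb`).
#' @param t weeks since last donation.
#' @param type `"mean"` for the linear predictor (g/L), `"prob"` for the
#'   probability of being over `threshold`.
#' @param threshold donation threshold in g/L, required for `type = "prob"`.
#' @param last_hb anchoring hemoglobin; defaults to `newdata$index_hb`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.recovery_model <- function(object, newdata, t,
                                   type = c("mean", "prob"), threshold = NULL,
                                   last_hb = newdata$index_hb, ...) {
  type <- match.arg(type)
  if (type == "mean") linear_predictor(object, newdata, t, last_hb)
  else {
    if (is.null(threshold)) stopf("threshold required for type = 'prob'")
    prob_over_threshold(object, newdata, t, threshold, last_hb)
  }
}

#' Simulate realized hemoglobin values from a recovery model
#'
#' @param object a [recovery_model()].
#' @param nsim number of replicate draws per donor.
#' @param seed optional seed.
#' @param donors donor table (with `latent_offset`).
#' @param t weeks since last donation.
#' @param last_hb anchoring hemoglobin.
#' @param ... unused.
#' @return if `nsim = 1` a numeric vector, else a matrix (donors x draws).
#' @export
simulate.recovery_model <- function(object, nsim = 1, seed = NULL,
                                    donors, t, last_hb = donors$index_hb, ...) {
  if (!is.null(seed)) {
    rs <- .restore_rng()
    on.exit(rs(), add = TRUE)
    set.seed(as.integer(seed %% .SEED_MOD))
  }
  out <- replicate(nsim, simulate_true_hb(object, donors, t, last_hb))
  if (nsim == 1) drop(out) else out
}
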