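#' Donor recall strategies
#'
#' The five modeled recall strategies:
#'
#' * **A** — current fixed recall: invitation at the regulatory floor
#'   (16 weeks women, 12 men), universal on-site hemoglobin screening,
#'   at most 4 invitations per year.
#' * **B** — post-donation testing, medium certainty: personalized interval at
#'   70% certainty of being over the threshold, floors 16/12, no on-site test.
#' * **C** — post-donation testing, high certainty: 90% certainty, floors
#'   16/12, no on-site test.
#' * **D** — high certainty with early recall permitted: 90% certainty with
#'   lowered floors of 12 weeks (women) / 8 weeks (men).
#' * **E** — medium certainty with limited on-site testing: recall at 70%
#'   certainty, with a portable on-site test administered to donors whose
#'   modeled probability lies in the medium band \[0.7, 0.9).
#'
#' @param name one of `"A"`–`"E"`.
#' @param min_interval,p_min,onsite_band,onsite_always,max_invitations_per_year,interval_cap
#'   overrides for the corresponding policy constants (floors per sex in
#'   weeks; required certainty; on-site probability band; universal on-site
#'   flag; yearly invitation cap; personalized-interval cap in weeks).
#' @return an object of class `recall_strategy`.
#' @examples
#' make_strategy("C")
#' @export
make_strategy <- function(name, min_interval = NULL, p_min = NULL,
                          onsite_band = NULL, onsite_always = NULL,
                          max_invitations_per_year = NULL,
                          interval_cap = 52) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("A", "B", "C", "D", "E"))
    stopf("unknown strategy '%s'; must be one of A, B, C, D, E", name)
  base <- switch(name,
    A = list(min_interval = c(female = 16, male = 12), p_min = NA_real_,
             onsite_band = NULL, onsite_always = TRUE, cap = 4L,
             label = "Current fixed recall"),
    B = list(min_interval = c(female = 16, male = 12), p_min = 0.7,
             onsite_band = NULL, onsite_always = FALSE, cap = 6L,
             label = "Medium certainty"),
    C = list(min_interval = c(female = 16, male = 12), p_min = 0.9,
             onsite_band = NULL, onsite_always = FALSE, cap = 6L,
             label = "High certainty"),
    D = list(min_interval = c(female = 12, male = 8), p_min = 0.9,
             onsite_band = NULL, onsite_always = FALSE, cap = 6L,
             label = "High certainty, early recall"),
    E = list(min_interval = c(female = 16, male = 12), p_min = 0.7,
             onsite_band = c(0.7, 0.9), onsite_always = FALSE, cap = 6L,
             label = "Medium certainty + on-site test"))
  spec <- list(name = name, label = base$label,
               min_interval = min_interval %||% base$min_interval,
               p_min = p_min %||% base$p_min,
               onsite_band = onsite_band %||% base$onsite_band,
               onsite_always = onsite_always %||% base$onsite_always,
               max_invitations_per_year =
                 as.integer(max_invitations_per_year %||% base$cap),
               interval_cap = interval_cap)
  if (any(spec$min_interval <= 0)) stopf("min_interval must be positive")
  if (!is.null(spec$onsite_band)) {
    if (length(spec$onsite_band) != 2L || spec$onsite_band[1] >= spec$onsite_band[2])
      stopf("onsite_band must be an increasing probability interval")
    if (!is.na(spec$p_min) && abs(spec$p_min - spec$onsite_band[1]) > 1e-12)
      stopf("p_min must equal the lower bound of the on-site band")
  }
  structure(spec, class = "recall_strategy")
}

#' @export
#' @method print recall_strategy
print.recall_strategy <- function(x, ...) {
  cat(sprintf("Recall strategy %s: %s\n", x$name, x$label))
  cat(sprintf("  floor %d w (women) / %d w (men); certainty %s; cap %d invitations/yr\n",
              x$min_interval[["female"]], x$min_interval[["male"]],
              if (is.na(x$p_min)) "none (fixed recall)" else
                sprintf("%.0f%%", 100 * x$p_min),
              x$max_invitations_per_year))
  if (x$onsite_always) cat("  on-site test: every attendance\n")
  else if (!is.null(x$onsite_band))
    cat(sprintf("  on-site test: modeled probability in [%.1f, %.1f)\n",
                x$onsite_band[1], x$onsite_band[2]))
  else cat("  on-site test: none\n")
  invisible(x)
}

#' Post-deferral re-invitation intervals
#'
#' Donors deferred for low hemoglobin are re-invited after 12 weeks, or 52
#' weeks when the modeled hemoglobin is very low (below 115 g/L women /
#' 125 g/L men); donors deferred for other reasons are re-invited after
#' 4 weeks.
#'
#' @param low_hb_weeks,low_hb_severe_weeks,other_weeks intervals in weeks.
#' @return an object of class `deferral_rules`.
#' @export
deferral_rules <- function(low_hb_weeks = 12, low_hb_severe_weeks = 52,
                           other_weeks = 4) {
  if (low_hb_severe_weeks < low_hb_weeks)
    stopf("severe low-hemoglobin deferral must be at least the standard one")
  structure(list(low_hb_weeks = low_hb_weeks,
                 low_hb_severe_weeks = low_hb_severe_weeks,
                 other_weeks = other_weeks), class = "deferral_rules")
}

#' Re-invitation interval after a deferral
#'
#' @param reason `"low_hb"` or `"other"`.
#' @param true_hb modeled hemoglobin at the deferral, g/L; required for
#'   low-hemoglobin deferrals to decide severity.
#' @param thresholds a [threshold_spec()].
#' @param rules a [deferral_rules()].
#' @return interval in weeks.
#' @export
deferral_reinvite_interval <- function(reason = c("low_hb", "other"),
                                       true_hb = NULL, thresholds,
                                       rules = deferral_rules()) {
  reason <- match.arg(reason)
  if (reason == "other") return(rules$other_weeks)
  if (is.null(true_hb) || is.na(true_hb))
    stopf("low-hemoglobin deferral requires the measured hemoglobin")
  if (true_hb < thresholds$severe_low) rules$low_hb_severe_weeks
  else rules$low_hb_weeks
}

#' Next invitation day after a donation
#'
#' Strategy A invites at the fixed floor; personalized strategies invite at
#' 7 days times the [personalized_interval()] solved from the hemoglobin
#' measured on the last donation (the post-donation analyzer value).
#'
#' @param strategy a [make_strategy()] spec.
#' @param model the donor's sex-stratum [recovery_model()].
#' @param donor single-row donor table.
#' @param last_donation_day day of the last donation (index donation = day 0).
#' @param last_hb analyzer hemoglobin at that donation, g/L.
#' @param thresholds a [threshold_spec()].
#' @return invitation day (integer days), with the `"capped"` attribute from
#'   the interval solver for personalized strategies.
#' @export
next_invitation_time <- function(strategy, model, donor, last_donation_day,
                                 last_hb, thresholds) {
  floor_w <- strategy$min_interval[[donor$sex]]
  if (is.na(strategy$p_min)) {
    w <- as.integer(floor_w)
    capped <- FALSE
  } else {
    w <- personalized_interval(model, donor, thresholds$donation_threshold,
                               p_min = strategy$p_min, t_min = floor_w,
                               t_max = strategy$interval_cap,
                               last_hb = last_hb)
    capped <- attr(w, "capped")
  }
  structure(as.integer(last_donation_day + 7L * as.integer(w)),
            interval_weeks = as.integer(w), capped = capped)
}

#' Does this attendance require an on-site hemoglobin test?
#'
#' Strategy A tests every attendance; B–D never test; E tests donors whose
#' modeled probability of being over the threshold — evaluated at the actual
#' attendance time, since the decision happens in session — falls in the
#' medium-certainty band.
#'
#' @inheritParams next_invitation_time
#' @param t_weeks weeks since the last donation at attendance.
#' @param at `"attendance"` (default) or `"invitation"`: when strategy E's
#'   band membership is evaluated.
#' @param t_invited weeks since last donation at the invited date (used when
#'   `at = "invitation"`).
#' @return logical.
#' @export
requires_onsite_test <- function(strategy, model, donor, t_weeks, last_hb,
                                 thresholds, at = c("attendance", "invitation"),
                                 t_invited = t_weeks) {
  if (strategy$onsite_always) return(TRUE)
  if (is.null(strategy$onsite_band)) return(FALSE)
  at <- match.arg(at)
  t_eval <- if (at == "attendance") t_weeks else t_invited
  p <- prob_over_threshold(model, donor, t_eval,
                           thresholds$donation_threshold, last_hb)
  p >= strategy$onsite_band[1] && p < strategy$onsite_band[2]
}
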