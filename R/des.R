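.OUTCOMES <- c("donated_over", "donated_under", "deferred_low_hb",
               "deferred_low_hb_severe", "deferred_other", "lapsed", "pending")
.INV_TYPES <- c("post_donation", "post_deferral")

#' Behavioral parameters of the simulated donor population
#'
#' Per-invitation dropout (donor lapse/withdrawal), per-attendance
#' non-hemoglobin deferral, the attendance-delay distribution (donors attend
#' at the invited week plus a non-negative geometric number of weeks), and the
#' on-site test error model. Default dropout and other-deferral rates are
#' calibrated to observed first-return rates per 1000 invited donors
#' (dropout 98/1000 women, 66/1000 men; other deferrals 49/902 women, 37/934
#' men) and applied identically at every recall.
#'
#' @param sex `"female"` or `"male"` (selects default rates).
#' @param dropout_prob probability a donor lapses at an invitation.
#' @param other_deferral_prob probability an attendee is deferred for a
#'   non-hemoglobin reason.
#' @param delay_mean_weeks mean of the geometric attendance delay, weeks.
#' @param delay_cap_weeks upper cap on the delay, weeks.
#' @param onsite_error list with `sigma_m` (g/L) and `c`: an under-threshold
#'   donor with deficit `d` g/L passes the on-site test (an inappropriate
#'   bleed) with probability `plogis(c - d / sigma_m)`; `c = -Inf` gives a
#'   perfect test.
#' @param hemocue_over_prob proportion of over-threshold strategy-A attendees
#'   who fail the initial gravimetric screen and therefore incur the venous
#'   on-site test cost.
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(sex = c("female", "male"),
                            dropout_prob = NULL,
                            other_deferral_prob = NULL,
                            delay_mean_weeks = 2,
                            delay_cap_weeks = 36,
                            onsite_error = list(sigma_m = 4, c = 1.5),
                            hemocue_over_prob = 0.1) {
  sex <- match.arg(sex)
  dropout_prob <- dropout_prob %||% if (sex == "female") 0.098 else 0.066
  other_deferral_prob <- other_deferral_prob %||%
    if (sex == "female") 49 / 902 else 37 / 934
  check_prob(dropout_prob, "dropout_prob")
  check_prob(other_deferral_prob, "other_deferral_prob")
  check_prob(hemocue_over_prob, "hemocue_over_prob")
  if (delay_mean_weeks < 0) stopf("delay_mean_weeks must be non-negative")
  structure(list(sex = sex, dropout_prob = dropout_prob,
                 other_deferral_prob = other_deferral_prob,
                 delay_mean_weeks = delay_mean_weeks,
                 delay_cap_weeks = delay_cap_weeks,
                 onsite_error = onsite_error,
                 hemocue_over_prob = hemocue_over_prob),
            class = "behavior_params")
}

#' On-site hemoglobin test outcome
#'
#' Donors whose true (modeled) hemoglobin is at or above the threshold always
#' pass. Under-threshold donors pass — an inappropriate bleed — with
#' probability `plogis(c - deficit / sigma_m)`, a non-increasing function of
#' the deficit, reflecting on-site measurement error; otherwise they fail and
#' are deferred for low hemoglobin.
#'
#' @param true_hb realized hemoglobin, g/L.
#' @param threshold donation threshold, g/L.
#' @param error_params list with `sigma_m` and `c` (see [behavior_params()]).
#' @return `"pass"` or `"fail"`. Draws from the current RNG stream.
#' @export
onsite_test_result <- function(true_hb, threshold,
                               error_params = list(sigma_m = 4, c = 1.5)) {
  if (true_hb >= threshold) return("pass")
  d <- threshold - true_hb
  p_pass <- stats::plogis(error_params$c - d / error_params$sigma_m)
  if (stats::runif(1) < p_pass) "pass" else "fail"
}

# Geometric attendance delay in whole weeks, mean `mean_w`, capped.
.draw_delay <- function(behavior) {
  m <- behavior$delay_mean_weeks
  if (m <= 0) return(0L)
  min(stats::rgeom(1, 1 / (1 + m)), as.integer(behavior$delay_cap_weeks))
}

# One invitation -> outcome. Returns a named list; draws from the current RNG
# stream (run_donor seeds one substream per donor).
.simulate_visit_impl <- function(donor, strategy, model, behavior, rules,
                                 thresholds, invitation_day, anchor_day,
                                 anchor_hb, horizon, carry_over) {
  ev <- list(invitation_day = invitation_day, attendance_day = NA_real_,
             t_weeks = NA_real_, true_hb = NA_real_, outcome = "lapsed",
             onsite_tested = FALSE, hemocue = FALSE, after_horizon = FALSE,
             reinvite_day = NA_real_, new_anchor_day = anchor_day,
             new_anchor_hb = anchor_hb)
  if (stats::runif(1) < behavior$dropout_prob) return(ev)

  att <- invitation_day + 7L * .draw_delay(behavior)
  if (att >= horizon && !carry_over) {
    ev$outcome <- "pending"
    return(ev)
  }
  ev$attendance_day <- att
  ev$after_horizon <- att >= horizon

  if (stats::runif(1) < behavior$other_deferral_prob) {
    ev$outcome <- "deferred_other"
    ev$reinvite_day <- att + 7 * rules$other_weeks
    return(ev)
  }

  t_w <- (att - anchor_day) / 7
  ev$t_weeks <- t_w
  hb <- simulate_true_hb(model, donor, t_w, last_hb = anchor_hb)
  ev$true_hb <- hb
  thr <- thresholds$donation_threshold

  test <- requires_onsite_test(strategy, model, donor, t_w, anchor_hb,
                               thresholds)
  ev$onsite_tested <- test
  if (test && onsite_test_result(hb, thr, behavior$onsite_error) == "fail") {
    severe <- hb < thresholds$severe_low
    ev$outcome <- if (severe) "deferred_low_hb_severe" else "deferred_low_hb"
    w <- deferral_reinvite_interval("low_hb", hb, thresholds, rules)
    ev$reinvite_day <- att + 7 * w
    return(ev)
  }

  # donation (all non-deferred attendees donate under post-donation testing;
  # under on-site testing, those passing the test donate)
  ev$outcome <- if (hb >= thr) "donated_over" else "donated_under"
  if (strategy$onsite_always) {
    ev$hemocue <- hb < thr ||
      stats::runif(1) < behavior$hemocue_over_prob
  }
  ev$new_anchor_day <- att
  ev$new_anchor_hb <- hb   # post-donation analyzer value anchors the next cycle
  ev
}

#' Simulate one invitation and its outcome
#'
#' Runs the visit sequence for a single invitation: lapse check, attendance
#' delay, non-hemoglobin deferral check, on-site test when the strategy
#' requires one, and outcome classification, with the donor's true hemoglobin
#' realized at the attendance time. Draws from the current RNG stream.
#'
#' @param donor single-row donor table.
#' @param strategy a [make_strategy()] spec.
#' @param model the sex-stratum [recovery_model()].
#' @param behavior a [behavior_params()].
#' @param rules a [deferral_rules()].
#' @param thresholds a [threshold_spec()].
#' @param invitation_day day the invitation falls due (index donation day 0).
#' @param anchor_day,anchor_hb day and analyzer hemoglobin of the last
#'   donation, anchoring the recovery trajectory.
#' @param horizon simulation horizon in days.
#' @param carry_over simulate attendances falling beyond the horizon (flagged
#'   `after_horizon`) rather than recording them as `pending`.
#' @return named list with the visit event fields (`outcome`,
#'   `attendance_day`, `true_hb`, `onsite_tested`, ...), the re-invitation day
#'   after a deferral, and the updated hemoglobin anchor after a donation.
#' @export
simulate_visit <- function(donor, strategy, model, behavior, rules,
                           thresholds, invitation_day, anchor_day = 0,
                           anchor_hb = donor$index_hb, horizon = 365,
                           carry_over = TRUE) {
  if (invitation_day >= horizon) stopf("invitation_day must precede horizon")
  .simulate_visit_impl(donor, strategy, model, behavior, rules, thresholds,
                       invitation_day, anchor_day, anchor_hb, horizon,
                       carry_over)
}

# Numeric event matrix for one donor; columns fixed for fast rbind.
.EV_COLS <- c("invitation_day", "attendance_day", "t_weeks", "true_hb",
              "outcome", "onsite_tested", "hemocue", "after_horizon",
              "inv_type", "interval_weeks", "capped")

.run_donor_mat <- function(donor, strategy, model, behavior, rules,
                           thresholds, horizon, carry_over) {
  cap <- strategy$max_invitations_per_year
  rows <- matrix(NA_real_, nrow = cap, ncol = length(.EV_COLS))
  k <- 0L
  anchor_day <- 0
  anchor_hb <- donor$index_hb
  inv <- next_invitation_time(strategy, model, donor, anchor_day, anchor_hb,
                              thresholds)
  inv_day <- as.numeric(inv)
  interval_w <- attr(inv, "interval_weeks")
  capped <- attr(inv, "capped")
  inv_type <- 1  # post_donation

  while (inv_day < horizon && k < cap) {
    ev <- .simulate_visit_impl(donor, strategy, model, behavior, rules,
                               thresholds, inv_day, anchor_day, anchor_hb,
                               horizon, carry_over)
    k <- k + 1L
    rows[k, ] <- c(inv_day, ev$attendance_day, ev$t_weeks, ev$true_hb,
                   match(ev$outcome, .OUTCOMES), ev$onsite_tested, ev$hemocue,
                   ev$after_horizon, inv_type,
                   if (inv_type == 1) interval_w else NA_real_,
                   if (inv_type == 1) as.numeric(capped) else NA_real_)
    if (ev$outcome %in% c("lapsed", "pending")) break
    if (!is.na(ev$reinvite_day)) {          # deferral: fixed re-invite, same anchor
      inv_day <- ev$reinvite_day
      inv_type <- 2
    } else {                                # donation: new anchor, strategy logic
      anchor_day <- ev$new_anchor_day
      anchor_hb <- ev$new_anchor_hb
      inv <- next_invitation_time(strategy, model, donor, anchor_day,
                                  anchor_hb, thresholds)
      inv_day <- as.numeric(inv)
      interval_w <- attr(inv, "interval_weeks")
      capped <- attr(inv, "capped")
      inv_type <- 1
    }
  }
  rows[seq_len(k), , drop = FALSE]
}

.mat_to_log <- function(mat, ids) {
  df <- as.data.frame(mat)
  names(df) <- .EV_COLS
  df$outcome <- factor(.OUTCOMES[df$outcome], levels = .OUTCOMES)
  df$onsite_tested <- df$onsite_tested > 0
  df$hemocue <- df$hemocue > 0
  df$after_horizon <- df$after_horizon > 0
  df$capped <- df$capped > 0
  df$inv_type <- factor(.INV_TYPES[df$inv_type], levels = .INV_TYPES)
  cbind(donor_id = ids, df)
}

#' Simulate one donor's year of recall events
#'
#' Iterates invitation, visit and re-invitation for a single donor from the
#' index donation at day 0 until the next invitation would fall at or beyond
#' the horizon or the strategy's invitation cap is reached. Invitations issued
#' before the horizon are simulated even when attendance falls after it
#' (flagged `after_horizon`).
#'
#' @inheritParams simulate_visit
#' @param seed integer seed for this donor's RNG substream.
#' @return data.frame of visit events, one row per invitation, time-ordered.
#' @export
run_donor <- function(donor, strategy, model, behavior, rules = deferral_rules(),
                      thresholds = threshold_spec(donor$sex), horizon = 365,
                      seed = 1, carry_over = TRUE) {
  rs <- .restore_rng()
  on.exit(rs(), add = TRUE)
  set.seed(as.integer(seed %% .SEED_MOD))
  mat <- .run_donor_mat(donor, strategy, model, behavior, rules, thresholds,
                        horizon, carry_over)
  .mat_to_log(mat, rep(donor$id, nrow(mat)))
}

#' Simulate a donor cohort under one recall strategy
#'
#' Runs the one-year discrete event simulation for every donor in a
#' (single-sex) population. Each donor receives an independent RNG substream
#' derived from the master seed and the donor's row position, so individual
#' trajectories do not depend on cohort size or ordering.
#'
#' @param population a single-sex `donor_population`.
#' @param strategy a [make_strategy()] spec.
#' @param model that sex's [recovery_model()]; defaults to
#'   [default_recovery_model()].
#' @param behavior a [behavior_params()] for that sex.
#' @param rules a [deferral_rules()].
#' @param thresholds a [threshold_spec()].
#' @param seed master integer seed.
#' @param horizon days (365 = the one-year design).
#' @param carry_over see [simulate_visit()].
#' @param costs a [cost_table()] used to attach per-event costs, or `NULL` to
#'   skip costing.
#' @return an `event_log`: data.frame of visit events with simulation
#'   metadata in `attr(, "meta")`.
#' @examples
#' pop <- generate_reference_population(population_config(n = 50), seed = 1,
#'                                      sex = "female")
#' log <- run_population(pop, make_strategy("C"), seed = 7)
#' summary(log)
#' @export
run_population <- function(population, strategy,
                           model = default_recovery_model(population$sex[1]),
                           behavior = behavior_params(population$sex[1]),
                           rules = deferral_rules(),
                           thresholds = threshold_spec(population$sex[1]),
                           seed = 1, horizon = 365, carry_over = TRUE,
                           costs = cost_table()) {
  if (nrow(population) == 0L) stopf("population is empty")
  sexes <- unique(population$sex)
  if (length(sexes) != 1L)
    stopf("run_population simulates one sex at a time (model and thresholds are sex-stratified); split the cohort")
  n <- nrow(population)
  seeds <- donor_seeds(seed, n)
  rs <- .restore_rng()
  on.exit(rs(), add = TRUE)
  mats <- vector("list", n)
  counts <- integer(n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    m <- .run_donor_mat(population[i, ], strategy, model, behavior, rules,
                        thresholds, horizon, carry_over)
    mats[[i]] <- m
    counts[i] <- nrow(m)
  }
  log <- .mat_to_log(do.call(rbind, mats), rep(population$id, counts))
  meta <- list(strategy = strategy, sex = sexes, n = n, seed = seed,
               horizon = horizon, thresholds = thresholds,
               behavior = behavior, model = model)
  log <- structure(log, meta = meta, class = c("event_log", "data.frame"))
  if (!is.null(costs)) log$cost_pence <- event_costs(log, strategy, costs)
  log
}

#' @export
#' @method print event_log
print.event_log <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Event log: strategy %s, %d %s donors, horizon %d days, seed %d\n",
              m$strategy$name, m$n, m$sex, m$horizon, m$seed))
  print(table(x$outcome))
  invisible(x)
}

#' Write an event log to CSV with a JSON metadata sidecar
#'
#' @param log an `event_log`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return the CSV path, invisibly.
#' @export
write_event_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  m <- attr(log, "meta")
  meta <- list(strategy = m$strategy$name, sex = m$sex, n = m$n,
               seed = m$seed, horizon = m$horizon)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
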