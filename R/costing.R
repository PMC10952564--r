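#' Unit costs to the blood service
#'
#' 2019 GBP unit costs applied per event: on-site venous spectrophotometry
#' test 1.08, off-site analyzer test 0.79, donation 26.49 (static venue,
#' including invitation letters and the initial gravimetric screen), low
#' hemoglobin deferral 9.21 (screening tests, staff time and downstream
#' care), other deferral 0.97. Held internally in integer pence so cost
#' accounting is exact.
#'
#' @param onsite_test,offsite_test,donation,deferral_low_hb,deferral_other
#'   unit costs in GBP; all must be non-negative.
#' @return an object of class `cost_table` (integer pence).
#' @export
cost_table <- function(onsite_test = 1.08, offsite_test = 0.79,
                       donation = 26.49, deferral_low_hb = 9.21,
                       deferral_other = 0.97) {
  v <- c(onsite_test = onsite_test, offsite_test = offsite_test,
         donation = donation, deferral_low_hb = deferral_low_hb,
         deferral_other = deferral_other)
  if (any(v < 0)) stopf("unit costs must be non-negative")
  structure(as.list(stats::setNames(to_pence(v), names(v))),
            class = "cost_table")
}

#' @export
#' @method print cost_table
print.cost_table <- function(x, ...) {
  cat("Unit costs (GBP):\n")
  for (nm in names(x)) cat(sprintf("  %-16s %6.2f\n", nm, x[[nm]] / 100))
  invisible(x)
}

#' Cost of one visit event
#'
#' Donations cost the donation unit cost, plus the off-site analyzer test
#' under post-donation strategies (every donation is analyzer-tested to plan
#' the next interval), plus the on-site test cost when one was administered
#' and paid for separately: under the fixed-recall strategy the venous on-site
#' test applies to the proportion of attendees failing the initial gravimetric
#' screen (all truly-under donors plus a configurable share of over-threshold
#' ones), and under the on-site-band strategy to every tested donation.
#' Deferral events carry their inclusive unit costs; lapses and pending
#' invitations cost nothing.
#'
#' @param event single visit event (one-row data.frame or list with `outcome`,
#'   `onsite_tested`, `hemocue`).
#' @param strategy the [make_strategy()] spec the event was simulated under.
#' @param costs a [cost_table()].
#' @return cost in GBP.
#' @export
cost_event <- function(event, strategy, costs = cost_table()) {
  ev <- as.data.frame(event)
  if (!ev$outcome %in% .OUTCOMES) stopf("unknown outcome '%s'", ev$outcome)
  event_costs(ev, strategy, costs) / 100
}

#' Vectorized per-event costs in integer pence
#'
#' @param log an `event_log` or data.frame of visit events.
#' @inheritParams cost_event
#' @return integer pence, one per event.
#' @export
event_costs <- function(log, strategy, costs = cost_table()) {
  out <- integer(nrow(log))
  donated <- log$outcome %in% c("donated_over", "donated_under")
  personalized <- !is.na(strategy$p_min)
  out[donated] <- costs$donation + if (personalized) costs$offsite_test else 0L
  onsite_paid <- donated &
    (if (strategy$onsite_always) log$hemocue else log$onsite_tested)
  out[onsite_paid] <- out[onsite_paid] + costs$onsite_test
  low <- log$outcome %in% c("deferred_low_hb", "deferred_low_hb_severe")
  out[low] <- costs$deferral_low_hb
  out[log$outcome == "deferred_other"] <- costs$deferral_other
  out
}

.BANDS <- list(
  female = list(breaks = c(-Inf, 12, 15, 16, 23, Inf),
                labels = c("12", "13-15", "16", "17-23", "24+")),
  male = list(breaks = c(-Inf, 8, 11, 12, 17, Inf),
              labels = c("8", "9-11", "12", "13-17", "18+")))

#' Inter-donation interval bands
#'
#' Reporting bands for invited inter-donation intervals: women 12, 13–15, 16,
#' 17–23 and 24+ weeks; men 8, 9–11, 12, 13–17 and 18+ weeks.
#'
#' @param intervals invited intervals in whole weeks.
#' @param sex `"female"` or `"male"`.
#' @return factor of band labels.
#' @export
interval_bands <- function(intervals, sex = c("female", "male")) {
  sex <- match.arg(sex)
  b <- .BANDS[[sex]]
  cut(intervals, breaks = b$breaks, labels = b$labels)
}

#' Summarize an event log into per-1000 outcome counts and costs
#'
#' Event counts scaled to `scale_to` donors, the adverse-event total
#' (donations under the threshold plus low hemoglobin deferrals), donations
#' per adverse event, mean cost per donation, and the distribution of invited
#' inter-donation intervals over the reporting bands (post-donation recall
#' invitations only; re-invitations after a deferral are excluded from the
#' band table).
#'
#' @param object an `event_log` from [run_population()].
#' @param scale_to report counts per this many donors (default 1000).
#' @param costs a [cost_table()], used if the log carries no cost column.
#' @param ... unused.
#' @return an `outcome_summary` list with elements `counts` (scaled),
#'   `adverse_events`, `donations_per_adverse_event`,
#'   `mean_cost_per_donation` (GBP; `NA` when there are no donations),
#'   `total_cost_gbp` (scaled), `interval_bands` (proportions summing to 1),
#'   `n`, `scale_to`, `strategy`, `sex`.
#' @export
#' @method summary event_log
summary.event_log <- function(object, scale_to = 1000, costs = cost_table(),
                              ...) {
  meta <- attr(object, "meta")
  if (nrow(object) == 0L) stopf("event log is empty")
  n <- meta$n
  f <- scale_to / n
  cnt <- function(cond) sum(cond)
  donations_over <- cnt(object$outcome == "donated_over")
  donations_under <- cnt(object$outcome == "donated_under")
  low_def <- cnt(object$outcome %in% c("deferred_low_hb",
                                       "deferred_low_hb_severe"))
  low_def_severe <- cnt(object$outcome == "deferred_low_hb_severe")
  other_def <- cnt(object$outcome == "deferred_other")
  lapses <- cnt(object$outcome == "lapsed")
  pending <- cnt(object$outcome == "pending")
  attendances <- cnt(!is.na(object$attendance_day))
  invitations <- nrow(object)

  pence <- if (!is.null(object$cost_pence)) object$cost_pence
           else event_costs(object, meta$strategy, costs)
  total_pence <- sum(pence)
  donations <- donations_over + donations_under
  adverse <- donations_under + low_def

  rec <- object$inv_type == "post_donation"
  bands <- interval_bands(object$interval_weeks[rec], meta$sex)
  band_prop <- if (length(bands)) as.numeric(prop.table(table(bands)))
               else rep(NA_real_, 5L)
  names(band_prop) <- .BANDS[[meta$sex]]$labels

  counts <- c(invitations = invitations, return_visits = attendances,
              donations_over = donations_over,
              donations_under = donations_under,
              low_hb_deferrals = low_def,
              low_hb_deferrals_severe = low_def_severe,
              other_deferrals = other_def, lapses = lapses,
              pending = pending) * f
  structure(list(
    counts = counts,
    adverse_events = (donations_under + low_def) * f,
    donations = donations * f,
    donations_per_adverse_event =
      if (adverse > 0) donations / adverse else NA_real_,
    mean_cost_per_donation =
      if (donations > 0) total_pence / 100 / donations else NA_real_,
    total_cost_gbp = total_pence / 100 * f,
    interval_bands = band_prop,
    n = n, scale_to = scale_to,
    strategy = meta$strategy$name, sex = meta$sex),
    class = "outcome_summary")
}

#' @export
#' @method print outcome_summary
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Outcome summary: strategy %s, %s, scaled to %d donors (n = %d)\n",
              x$strategy, x$sex, x$scale_to, x$n))
  cat("  Events per", x$scale_to, "donors:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-24s %8.1f\n", nm, x$counts[[nm]]))
  cat(sprintf("  Adverse events:             %8.1f\n", x$adverse_events))
  cat(sprintf("  Donations per adverse event:%8.1f\n",
              x$donations_per_adverse_event))
  cat(sprintf("  Mean cost per donation:     GBP %.2f\n",
              x$mean_cost_per_donation))
  cat("  Invited interval bands (weeks):\n")
  for (nm in names(x$interval_bands))
    cat(sprintf("    %-8s %6.1f%%\n", nm, 100 * x$interval_bands[[nm]]))
  invisible(x)
}

#' Donations per adverse event
#'
#' The safety/efficiency ratio: total donations (over plus under the
#' threshold) divided by adverse events (under-threshold donations plus low
#' hemoglobin deferrals).
#'
#' @param x an `outcome_summary`, or the count of over-threshold donations.
#' @param under,low_hb counts of under-threshold donations and low hemoglobin
#'   deferrals, when `x` is a count.
#' @return the ratio; `NA` when there are no adverse events.
#' @examples
#' donations_per_adverse_event(665, 114, 66)  # 779/180 = 4.33
#' @export
donations_per_adverse_event <- function(x, under = NULL, low_hb = NULL) {
  if (inherits(x, "outcome_summary")) return(x$donations_per_adverse_event)
  adverse <- under + low_hb
  if (adverse <= 0) return(NA_real_)
  (x + under) / adverse
}

#' First-return internal-validation simulation
#'
#' Simulates exactly one invitation cycle per donor under a fixed-recall
#' strategy variant whose floor for women is lowered to 12 weeks, reflecting
#' that a minority of women historically returned between 12 and 16 weeks
#' although advised to wait 16. Used to compare predicted first-return event
#' counts against observed per-1000 counts.
#'
#' @inheritParams run_population
#' @param female_floor_weeks women's minimum return interval in this mode.
#' @return an `event_log` with at most one event per donor.
#' @export
first_return_mode <- function(population, strategy = make_strategy("A"),
                              model = default_recovery_model(population$sex[1]),
                              behavior = behavior_params(population$sex[1]),
                              rules = deferral_rules(),
                              thresholds = threshold_spec(population$sex[1]),
                              seed = 1, female_floor_weeks = 12) {
  st <- strategy
  st$min_interval[["female"]] <- female_floor_weeks
  st$max_invitations_per_year <- 1L
  run_population(population, st, model, behavior, rules, thresholds,
                 seed = seed)
}

.VALIDATION_CATS <- c("dropout", "returned", "other_deferrals",
                      "donations_over", "donations_under",
                      "low_hb_deferrals")

#' Per-1000 first-return counts from an event log
#'
#' @param log an `event_log` from [first_return_mode()].
#' @param scale_to per how many donors.
#' @return named numeric over the validation categories.
#' @export
first_return_counts <- function(log, scale_to = 1000) {
  s <- summary(log, scale_to = scale_to)
  c(dropout = unname(s$counts[["lapses"]]),
    returned = unname(s$counts[["return_visits"]]),
    other_deferrals = unname(s$counts[["other_deferrals"]]),
    donations_over = unname(s$counts[["donations_over"]]),
    donations_under = unname(s$counts[["donations_under"]]),
    low_hb_deferrals = unname(s$counts[["low_hb_deferrals"]]))
}

#' Observed first-return event counts fixture
#'
#' Per-1000 observed first-return counts (dropout, returned, other deferrals,
#' over/under-threshold donations, low hemoglobin deferrals) for women and
#' men, packaged as the reference for the internal-validation comparison.
#'
#' @return data.frame with columns `sex`, `category`, `count`.
#' @export
observed_first_return <- function() {
  path <- system.file("extdata", "observed_first_return_counts.csv",
                      package = "donorecall", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Predicted vs observed validation report
#'
#' Per category, the percent difference `round(100 * (predicted - observed) /
#' observed)` to the nearest integer, plus the donations-per-adverse-event
#' ratio for each side (no difference is reported for the ratio).
#'
#' @param predicted named per-1000 counts over the validation categories
#'   (see [first_return_counts()]), or an `event_log` from
#'   [first_return_mode()].
#' @param observed named per-1000 counts over the same categories.
#' @return data.frame with columns `category`, `observed`, `predicted`,
#'   `pct_difference` (`NA` for the ratio row and for zero observed counts).
#' @examples
#' obs <- c(dropout = 98, returned = 902, other_deferrals = 49,
#'          donations_over = 658, donations_under = 125, low_hb_deferrals = 69)
#' validation_report(obs * 0.96, obs)
#' @export
validation_report <- function(predicted, observed) {
  if (inherits(predicted, "event_log")) predicted <- first_return_counts(predicted)
  miss <- setdiff(.VALIDATION_CATS, names(predicted))
  if (length(miss))
    stopf("predicted counts lack categories: %s", paste(miss, collapse = ", "))
  miss <- setdiff(.VALIDATION_CATS, names(observed))
  if (length(miss))
    stopf("observed counts lack categories: %s", paste(miss, collapse = ", "))
  p <- unname(predicted[.VALIDATION_CATS])
  o <- unname(observed[.VALIDATION_CATS])
  pct <- ifelse(o == 0, NA_real_, round(100 * (p - o) / o))
  ratio_p <- donations_per_adverse_event(p[4], p[5], p[6])
  ratio_o <- donations_per_adverse_event(o[4], o[5], o[6])
  out <- data.frame(
    category = c(.VALIDATION_CATS, "donations_per_adverse_event"),
    observed = c(o, round(ratio_o, 1)),
    predicted = c(p, round(ratio_p, 1)),
    pct_difference = c(pct, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
#' @method print validation_report
print.validation_report <- function(x, ...) {
  cat("Internal validation (per 1000 donors):\n")
  df <- as.data.frame(x)
  df$pct_difference <- ifelse(is.na(df$pct_difference), "-",
                              sprintf("%+d%%", df$pct_difference))
  print(df, row.names = FALSE)
  invisible(x)
}
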