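test_that("on-site test passes over-threshold donors and obeys the error law", {
  set.seed(1)
  expect_identical(onsite_test_result(125, 125), "pass")
  expect_identical(onsite_test_result(140, 125), "pass")
  # perfect test: every under-threshold donor fails
  perfect <- list(sigma_m = 4, c = -Inf)
  for (i in 1:50)
    expect_identical(onsite_test_result(124.9, 125, perfect), "fail")
  # false-pass probability decreases with the deficit
  set.seed(2)
  pass_rate <- function(deficit, n = 2000)
    mean(replicate(n, onsite_test_result(125 - deficit, 125)) == "pass")
  expect_gt(pass_rate(1), pass_rate(20) + 0.3)
})

test_that("a certain dropout produces a lapse with no attendance", {
  d <- toy_donor()
  ev <- simulate_visit(d, make_strategy("B"), toy_model(),
                       behavior_params("female", dropout_prob = 1),
                       deferral_rules(), threshold_spec("female"),
                       invitation_day = 112)
  expect_identical(ev$outcome, "lapsed")
  expect_true(is.na(ev$attendance_day))
})

test_that("post-donation strategies bleed under-threshold attendees", {
  # true Hb forced under: zero noise, weak anchor
  m <- toy_model(intercept = 20, coef_index_hb = 0.7, slope = 0,
                 latent_sd = 0, residual_sd = 0)
  d <- toy_donor(index_hb = 130)          # mu = 20 + 91 = 111 < 125
  set.seed(3)
  ev <- simulate_visit(d, make_strategy("B"), m, quiet_behavior(),
                       deferral_rules(), threshold_spec("female"),
                       invitation_day = 112)
  expect_identical(ev$outcome, "donated_under")
  expect_false(ev$onsite_tested)
  expect_lt(ev$true_hb, 125)
})

test_that("on-site failures defer with severity-dependent re-invitation", {
  tf <- threshold_spec("female")
  rules <- deferral_rules()
  beh <- quiet_behavior(onsite_error = list(sigma_m = 4, c = -Inf))
  # moderate low: 115 <= Hb < 125 -> 12 weeks
  m1 <- toy_model(intercept = 30, coef_index_hb = 0.7, slope = 0,
                  latent_sd = 0, residual_sd = 0)
  d <- toy_donor(index_hb = 130)          # true Hb = 121
  set.seed(4)
  ev <- simulate_visit(d, make_strategy("A"), m1, beh, rules, tf, 112)
  expect_identical(ev$outcome, "deferred_low_hb")
  expect_true(ev$onsite_tested)
  expect_equal(ev$reinvite_day, ev$attendance_day + 7 * 12)
  # severe low: Hb < 115 -> 52 weeks
  m2 <- toy_model(intercept = 10, coef_index_hb = 0.7, slope = 0,
                  latent_sd = 0, residual_sd = 0)   # true Hb = 101
  set.seed(5)
  ev2 <- simulate_visit(d, make_strategy("A"), m2, beh, rules, tf, 112)
  expect_identical(ev2$outcome, "deferred_low_hb_severe")
  expect_equal(ev2$reinvite_day, ev2$attendance_day + 7 * 52)
})

test_that("a donor lapsing at the first invitation leaves a single event", {
  d <- toy_donor()
  log <- run_donor(d, make_strategy("A"), toy_model(),
                   behavior_params("female", dropout_prob = 1),
                   seed = 6)
  expect_identical(nrow(log), 1L)
  expect_identical(as.character(log$outcome), "lapsed")
})

test_that("fixed recall with immediate attendance yields the 16-week calendar", {
  d <- toy_donor(index_hb = 150)
  m <- toy_model(intercept = 60, coef_index_hb = 0.7, slope = 0.3,
                 latent_sd = 0, residual_sd = 0)   # always well over threshold
  log <- run_donor(d, make_strategy("A"), m, quiet_behavior(), seed = 7)
  expect_identical(log$invitation_day, c(112, 224, 336))
  expect_identical(log$attendance_day, c(112, 224, 336))
  expect_true(all(log$outcome == "donated_over"))
})

test_that("donor runs are reproducible and respect the invitation cap", {
  d <- toy_donor()
  m <- default_recovery_model("female")
  b <- behavior_params("female")
  a <- run_donor(d, make_strategy("A"), m, b, seed = 8)
  b2 <- run_donor(d, make_strategy("A"), m, b, seed = 8)
  expect_identical(a, b2)
  expect_lte(nrow(a), 4L)

  # deferral re-invites count toward the cap and cannot exceed it
  beh_defer <- quiet_behavior(onsite_error = list(sigma_m = 4, c = -Inf))
  m_low <- toy_model(intercept = 28, coef_index_hb = 0.7, slope = 0,
                     latent_sd = 0, residual_sd = 0)  # perpetually under
  log <- run_donor(d, make_strategy("A"), m_low, beh_defer, seed = 9)
  expect_lte(nrow(log), 4L)
  expect_true(all(log$outcome == "deferred_low_hb"))
})

test_that("population runs are deterministic and match the donor substream", {
  pop <- small_population(n = 60, seed = 51)
  st <- make_strategy("C")
  m <- default_recovery_model("female")
  b <- behavior_params("female")
  log1 <- run_population(pop, st, m, b, seed = 99)
  log2 <- run_population(pop, st, m, b, seed = 99)
  expect_identical(as.data.frame(log1), as.data.frame(log2))

  one <- pop[1, ]
  solo <- run_population(one, st, m, b, seed = 99)
  direct <- run_donor(one, st, m, b,
                      seed = donorecall:::donor_seeds(99, 1)[1])
  plain <- function(x, cols) {
    y <- as.data.frame(x)[cols]
    attr(y, "meta") <- NULL
    class(y) <- "data.frame"
    rownames(y) <- NULL
    y
  }
  expect_equal(plain(solo, names(direct)), plain(direct, names(direct)))

  # a donor's trajectory does not depend on cohort size
  expect_equal(plain(log1[log1$donor_id == pop$id[1], ], names(direct)),
               plain(direct, names(direct)))
})

test_that("event accounting is conserved and policies test whom they should", {
  pop <- small_population(n = 2000, seed = 52)
  for (st_name in c("A", "B", "E")) {
    log <- run_population(pop, make_strategy(st_name), seed = 13)
    invitations <- nrow(log)
    lapses <- sum(log$outcome == "lapsed")
    pending <- sum(log$outcome == "pending")
    attendances <- sum(!is.na(log$attendance_day))
    expect_identical(invitations, lapses + attendances + pending)
    donations <- sum(log$outcome %in% c("donated_over", "donated_under"))
    low <- sum(log$outcome %in% c("deferred_low_hb", "deferred_low_hb_severe"))
    other <- sum(log$outcome == "deferred_other")
    expect_identical(attendances, donations + low + other)

    att <- !is.na(log$attendance_day) & log$outcome != "deferred_other"
    if (st_name == "A") expect_true(all(log$onsite_tested[att]))
    if (st_name == "B") {
      expect_false(any(log$onsite_tested))
      expect_identical(low, 0L)
    }
  }
})

test_that("per-donor event times increase and respect the strategy floor", {
  pop <- small_population(n = 500, seed = 53)
  log <- run_population(pop, make_strategy("D"), seed = 14)
  for (id in unique(log$donor_id)) {
    ev <- log[log$donor_id == id, ]
    expect_true(all(diff(ev$invitation_day) > 0))
  }
  rec <- log$inv_type == "post_donation"
  expect_true(all(log$interval_weeks[rec] >= 12))  # women's floor under D
})

test_that("first-return lapses match the binomial rate", {
  pop <- small_population(n = 10000, seed = 54)
  log <- first_return_mode(pop, seed = 15)
  counts <- first_return_counts(log)
  p <- 0.098
  se <- sqrt(p * (1 - p) / 10000) * 1000
  expect_lt(abs(counts[["dropout"]] - 98), 3 * se)
})

test_that("horizon semantics: pending only without carry-over, flags with it", {
  d <- toy_donor()
  m <- default_recovery_model("female")
  beh <- behavior_params("female", dropout_prob = 0,
                         other_deferral_prob = 0, delay_mean_weeks = 30,
                         delay_cap_weeks = 60)
  log <- run_donor(d, make_strategy("A"), m, beh, seed = 16)
  expect_true(all(log$after_horizon[!is.na(log$attendance_day) &
                                      log$attendance_day >= 365]))
  log_strict <- run_donor(d, make_strategy("A"), m, beh, seed = 16,
                          carry_over = FALSE)
  expect_true(any(log_strict$outcome == "pending"))
})
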