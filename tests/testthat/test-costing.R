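test_that("unit costs combine per event as the cost model states", {
  costs <- cost_table()
  B <- make_strategy("B")
  A <- make_strategy("A")
  E <- make_strategy("E")
  ev <- function(outcome, onsite = FALSE, hemocue = FALSE)
    data.frame(outcome = factor(outcome, levels = donorecall:::.OUTCOMES),
               onsite_tested = onsite, hemocue = hemocue)
  # post-donation strategy: donation + analyzer test
  expect_equal(cost_event(ev("donated_over"), B, costs), 26.49 + 0.79)
  expect_equal(cost_event(ev("donated_under"), B, costs), 27.28)
  # fixed recall: donation alone, venous on-site test only when administered
  expect_equal(cost_event(ev("donated_over", onsite = TRUE), A, costs), 26.49)
  expect_equal(cost_event(ev("donated_under", onsite = TRUE, hemocue = TRUE),
                          A, costs), 26.49 + 1.08)
  # on-site band strategy: tested donations carry the portable-test cost
  expect_equal(cost_event(ev("donated_over", onsite = TRUE), E, costs),
               26.49 + 0.79 + 1.08)
  expect_equal(cost_event(ev("deferred_low_hb"), B, costs), 9.21)
  expect_equal(cost_event(ev("deferred_other"), B, costs), 0.97)
  expect_equal(cost_event(ev("lapsed"), B, costs), 0)
  expect_error(cost_event(data.frame(outcome = "won"), B, costs), "unknown")
})

test_that("total cost equals the unit-cost ledger exactly, in pence", {
  pop <- small_population(n = 2000, seed = 55)
  costs <- cost_table()
  for (st_name in c("A", "C", "E")) {
    st <- make_strategy(st_name)
    log <- run_population(pop, st, seed = 17)
    personalized <- !is.na(st$p_min)
    donated <- log$outcome %in% c("donated_over", "donated_under")
    onsite_paid <- donated & (if (st$onsite_always) log$hemocue
                              else log$onsite_tested)
    ledger <- sum(donated) * (costs$donation +
                                if (personalized) costs$offsite_test else 0L) +
      sum(onsite_paid) * costs$onsite_test +
      sum(log$outcome %in% c("deferred_low_hb", "deferred_low_hb_severe")) *
        costs$deferral_low_hb +
      sum(log$outcome == "deferred_other") * costs$deferral_other
    expect_identical(sum(log$cost_pence), as.integer(ledger))
  }
})

test_that("post-donation mean cost per donation is the closed-form identity", {
  pop <- small_population(n = 3000, seed = 56)
  for (st_name in c("B", "C", "D")) {
    log <- run_population(pop, make_strategy(st_name), seed = 18)
    s <- summary(log)
    other <- sum(log$outcome == "deferred_other")
    donations <- sum(log$outcome %in% c("donated_over", "donated_under"))
    expect_equal(s$mean_cost_per_donation,
                 27.28 + 0.97 * other / donations, tolerance = 1e-12)
  }
})

test_that("summaries scale per 1000, bands normalize, empty donations guard", {
  pop <- small_population(n = 1500, seed = 57)
  log <- run_population(pop, make_strategy("B"), seed = 19)
  s <- summary(log)
  expect_equal(sum(s$interval_bands), 1, tolerance = 1e-12)
  expect_named(s$interval_bands, c("12", "13-15", "16", "17-23", "24+"))
  # doubling the cohort leaves per-1000 rates unchanged within noise
  pop2 <- small_population(n = 3000, seed = 57)
  s2 <- summary(run_population(pop2, make_strategy("B"), seed = 19))
  expect_lt(abs(s$donations - s2$donations) / s2$donations, 0.10)

  all_lapse <- run_population(pop, make_strategy("B"),
                              behavior = behavior_params("female",
                                                         dropout_prob = 1),
                              seed = 20)
  sl <- summary(all_lapse)
  expect_equal(unname(sl$counts[["donations_over"]]), 0)
  expect_true(is.na(sl$mean_cost_per_donation))
  expect_true(is.na(sl$donations_per_adverse_event))
})

test_that("men's interval bands use the 8/12-week grid", {
  pop <- small_population(n = 800, sex = "male", seed = 58)
  s <- summary(run_population(pop, make_strategy("D"), seed = 21))
  expect_named(s$interval_bands, c("8", "9-11", "12", "13-17", "18+"))
  sA <- summary(run_population(pop, make_strategy("A"), seed = 21))
  expect_equal(unname(sA$interval_bands[["12"]]), 1)  # fixed 12-week recall
})

test_that("donations per adverse event reproduces printed-table arithmetic", {
  expect_equal(round(donations_per_adverse_event(665, 114, 66), 1), 4.3)
  expect_equal(round(donations_per_adverse_event(816, 51, 21), 1), 12.0)
  expect_true(is.na(donations_per_adverse_event(500, 0, 0)))
})

test_that("validation percent differences follow the rounding convention", {
  obs <- c(dropout = 98, returned = 902, other_deferrals = 49,
           donations_over = 658, donations_under = 125,
           low_hb_deferrals = 69)
  idn <- validation_report(obs, obs)
  expect_true(all(idn$pct_difference[seq_len(6)] == 0))
  pred <- obs
  pred["donations_under"] <- 51
  obs2 <- obs
  obs2["donations_under"] <- 68
  rep2 <- validation_report(pred, obs2)
  expect_equal(rep2$pct_difference[rep2$category == "donations_under"], -25)
  pred3 <- obs
  pred3["low_hb_deferrals"] <- 66
  obs3 <- obs
  obs3["low_hb_deferrals"] <- 69
  rep3 <- validation_report(pred3, obs3)
  expect_equal(rep3$pct_difference[rep3$category == "low_hb_deferrals"], -4)
  # zero observed count: undefined sentinel
  obs0 <- obs
  obs0["low_hb_deferrals"] <- 0
  expect_true(is.na(validation_report(obs, obs0)$pct_difference[6]))
})

test_that("first-return mode makes one cycle with a 12-week women's floor", {
  pop <- small_population(n = 3000, seed = 59)
  log <- first_return_mode(pop, seed = 23)
  expect_lte(max(table(log$donor_id)), 1L)
  expect_true(all(log$invitation_day == 84))
  att <- log$attendance_day[!is.na(log$attendance_day)]
  expect_gte(min(att), 84)
})
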