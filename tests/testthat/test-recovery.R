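test_that("linear predictor is linear in time and matches hand arithmetic", {
  d <- toy_donor(index_hb = 130)
  m0 <- toy_model(slope = 0)
  expect_equal(linear_predictor(m0, d, 0), linear_predictor(m0, d, 40))

  m <- toy_model(slope = 0.4)
  expect_equal(linear_predictor(m, d, 10) - linear_predictor(m, d, 0), 4.0)

  # independent dot-product computation on a fully specified donor
  mfull <- recovery_model("female", intercept = 20, coef_index_hb = 0.8,
                          slope = 0.25, age_coef = -0.1, age_ref = 45,
                          ethnicity_effects = c(White = 0, Black = 1.5),
                          blood_group_effects = c(`O+` = 0, `O-` = 0.5),
                          latent_sd = 3, residual_sd = 5)
  donor <- toy_donor(index_hb = 128, age = 52, ethnicity = "Black",
                     blood_group = "O-")
  by_hand <- 20 + 0.8 * 128 + (-0.1) * (52 - 45) + 1.5 + 0.5 + 0.25 * 9
  expect_equal(linear_predictor(mfull, donor, 9), by_hand, tolerance = 1e-12)

  expect_error(linear_predictor(mfull, toy_donor(ethnicity = "Unknown"), 1),
               "unknown ethnicity")
  expect_error(linear_predictor(mfull, donor, -1), "non-negative")
})

test_that("threshold-crossing probability follows the normal predictive law", {
  m <- toy_model(latent_sd = 3, residual_sd = 4)     # sigma_pred = 5
  s <- predictive_sd(m)
  expect_equal(s, 5)
  d <- toy_donor()
  mu <- linear_predictor(m, d, 10)
  expect_equal(prob_over_threshold(m, d, 10, threshold = mu), 0.5)
  expect_equal(prob_over_threshold(m, d, 10, threshold = mu - s), pnorm(1))
  expect_gt(prob_over_threshold(m, d, 10, threshold = mu - 5 * s), 0.999)

  # degenerate sigma: step function
  m0 <- toy_model(latent_sd = 0, residual_sd = 0)
  mu0 <- linear_predictor(m0, d, 10)
  expect_identical(prob_over_threshold(m0, d, 10, mu0), 1)
  expect_identical(prob_over_threshold(m0, d, 10, mu0 + 0.01), 0)
})

test_that("crossing probability is monotone in time, anchor and threshold", {
  m <- toy_model(slope = 0.3)
  d <- toy_donor(index_hb = 125)
  t <- 0:52
  p <- prob_over_threshold(m, d, t, 125)
  expect_true(all(diff(p) >= 0))
  hb <- seq(105, 160, by = 0.5)
  p_hb <- vapply(hb, function(h)
    prob_over_threshold(m, d, 12, 125, last_hb = h), numeric(1))
  expect_true(all(diff(p_hb) >= 0))
  thr <- seq(110, 140, by = 0.5)
  p_thr <- vapply(thr, function(x)
    prob_over_threshold(m, d, 12, x), numeric(1))
  expect_true(all(diff(p_thr) <= 0))
})

test_that("interval solver returns the floor when certainty is already met", {
  m <- default_recovery_model("female")
  strong <- toy_donor(index_hb = 150)
  for (p_min in c(0.7, 0.9)) {
    w <- personalized_interval(m, strong, 125, p_min, t_min = 16, t_max = 52)
    expect_identical(as.integer(w), 16L)
    expect_false(attr(w, "capped"))
  }
})

test_that("non-crossing trajectories are capped and flagged", {
  m <- toy_model(slope = 0, latent_sd = 3, residual_sd = 4)
  weak <- toy_donor(index_hb = 100)
  w <- personalized_interval(m, weak, 125, 0.9, t_min = 16, t_max = 52)
  expect_identical(as.integer(w), 52L)
  expect_true(attr(w, "capped"))
})

test_that("closed-form interval solver agrees exactly with a weekly scan", {
  set.seed(404)
  n <- 1000
  pop <- small_population(n = n, seed = 404)
  models <- list(default_recovery_model("female"),
                 toy_model(slope = 0.15, latent_sd = 2, residual_sd = 7),
                 toy_model(slope = 0, latent_sd = 3, residual_sd = 4))
  for (m in models) {
    p_min <- sample(c(0.7, 0.9), n, replace = TRUE)
    for (i in seq_len(min(n, if (m$slope == 0) 100 else n))) {
      d <- pop[i, ]
      got <- personalized_interval(m, d, 125, p_min[i], t_min = 12, t_max = 52)
      want <- brute_force_interval(m, d, 125, p_min[i], 12, 52)
      expect_identical(as.integer(got), as.integer(want$weeks))
      expect_identical(unname(attr(got, "capped")), want$capped)
    }
  }
})

test_that("intervals are monotone in anchor hemoglobin and certainty", {
  m <- default_recovery_model("female")
  hb <- seq(110, 150, by = 1)
  w <- vapply(hb, function(h) {
    d <- toy_donor(index_hb = h)
    as.integer(personalized_interval(m, d, 125, 0.9, 16, 52))
  }, integer(1))
  expect_true(all(diff(w) <= 0))

  pop <- small_population(n = 200, seed = 31)
  w70 <- personalized_interval(m, pop, 125, 0.7, 16, 52)
  w90 <- personalized_interval(m, pop, 125, 0.9, 16, 52)
  expect_true(all(w90 >= w70))
})

test_that("true hemoglobin simulation respects the variance decomposition", {
  d <- toy_donor(latent_offset = 2.5)
  m0 <- toy_model(latent_sd = 0, residual_sd = 0)
  expect_equal(simulate_true_hb(m0, toy_donor(), 8),
               linear_predictor(m0, toy_donor(), 8))
  # the latent offset persists across visits of the same donor
  expect_equal(simulate_true_hb(m0, d, 8) - linear_predictor(m0, d, 8), 2.5)
  expect_equal(simulate_true_hb(m0, d, 20) - linear_predictor(m0, d, 20), 2.5)

  m <- toy_model(latent_sd = 3, residual_sd = 4)
  n <- 10000
  pop <- small_population(n = n, seed = 5,
                          latent_sd = 3)
  set.seed(77)
  draws <- simulate_true_hb(m, pop, 10)
  resid <- draws - linear_predictor(m, pop, 10)
  expect_lt(abs(sd(resid) - 5) / 5, 0.03)
})

test_that("model constructor and thresholds validate their invariants", {
  expect_error(recovery_model("female", 50, 0.6, 0.3, latent_sd = -1,
                              residual_sd = 6), "non-negative")
  expect_error(threshold_spec("female", donation_threshold = 125,
                              severe_low = 130), "below")
  ts <- threshold_spec("male")
  expect_equal(ts$donation_threshold, 135)
  expect_equal(ts$severe_low, 125)
  tf <- threshold_spec("female")
  expect_equal(tf$donation_threshold, 125)
  expect_equal(tf$severe_low, 115)
})
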