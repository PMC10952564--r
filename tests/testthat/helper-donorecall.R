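# Shared fixture builders. Everything is generated in code; tests that need
# reproducibility pass explicit seeds.

# A donor with known fields for hand arithmetic.
toy_donor <- function(sex = "female", index_hb = 134, age = 45,
                      ethnicity = "White", blood_group = "O+",
                      latent_offset = 0, id = 1L) {
  structure(data.frame(id = id, sex = sex, age = age, ethnicity = ethnicity,
                       blood_group = blood_group, index_hb = index_hb,
                       latent_offset = latent_offset,
                       stringsAsFactors = FALSE),
            class = c("donor_population", "data.frame"))
}

# A minimal model with controllable pieces; all covariate effects zero so the
# predictor depends only on the anchor hemoglobin, age and time.
toy_model <- function(sex = "female", intercept = 50, coef_index_hb = 0.6,
                      slope = 0.3, age_coef = 0, latent_sd = 4,
                      residual_sd = 6) {
  zeros <- function(levels) stats::setNames(numeric(length(levels)), levels)
  recovery_model(sex, intercept = intercept, coef_index_hb = coef_index_hb,
                 slope = slope, age_coef = age_coef,
                 ethnicity_effects = zeros(c("White", "Asian", "Black",
                                             "MixedOther")),
                 blood_group_effects = zeros(c("O+", "O-", "A+", "A-", "B+",
                                               "B-", "AB+", "AB-")),
                 latent_sd = latent_sd, residual_sd = residual_sd)
}

# Deterministic behavior: nobody lapses or is deferred, attendance immediate.
quiet_behavior <- function(sex = "female", ...) {
  behavior_params(sex, dropout_prob = 0, other_deferral_prob = 0,
                  delay_mean_weeks = 0, ...)
}

small_population <- function(n = 200, sex = "female", seed = 11, ...) {
  generate_reference_population(population_config(n = n, ...), seed = seed,
                                sex = sex)
}

# Week-by-week scan: the independent oracle for the interval solver.
brute_force_interval <- function(model, donor, threshold, p_min, t_min, t_max) {
  for (t in seq.int(t_min, t_max)) {
    if (prob_over_threshold(model, donor, t, threshold) >= p_min)
      return(list(weeks = t, capped = FALSE))
  }
  list(weeks = t_max, capped = TRUE)
}
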