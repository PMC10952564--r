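# Default configuration. Keys marked "assumed: true" are plausible synthetic
# values standing in for unavailable cohort estimates; all others encode
# policy constants or published unit costs.

population:
  n_donors: 10000
  sex_mix: {female: 0.5, male: 0.5}
  index_hb:
    assumed: true
    female: {mean: 134.0, sd: 10.0}
    male: {mean: 149.0, sd: 11.0}
  index_hb_floor: 100.0
  age: {assumed: true, mean: 45.0, sd: 13.0, min: 18, max: 70}
  ethnicity_freq:
    assumed: true
    White: 0.88
    Asian: 0.05
    Black: 0.04
    MixedOther: 0.03
  blood_group_freq:
    assumed: true
    "O+": 0.35
    "O-": 0.13
    "A+": 0.30
    "A-": 0.08
    "B+": 0.08
    "B-": 0.02
    "AB+": 0.03
    "AB-": 0.01

model:
  assumed: true
  female:
    intercept: 16.3
    coef_index_hb: 0.85
    slope: 0.3
    age_coef: -0.05
    age_ref: 45.0
    latent_sd: 3.5
    residual_sd: 4.5
  male:
    intercept: 17.75
    coef_index_hb: 0.85
    slope: 0.3
    age_coef: -0.05
    age_ref: 45.0
    latent_sd: 3.5
    residual_sd: 4.5
  ethnicity_effects: {White: 0.0, Asian: -1.0, Black: 1.5, MixedOther: 0.5}
  blood_group_effects:
    "O+": 0.0
    "O-": 0.5
    "A+": 0.0
    "A-": 0.5
    "B+": -0.5
    "B-": 0.0
    "AB+": -0.5
    "AB-": 0.0
  se:
    intercept: 1.5
    coef_index_hb: 0.01
    slope: 0.03
    age_coef: 0.005
    latent_sd: 0.2
    residual_sd: 0.15

behavior:
  # dropout / other-deferral rates calibrated to observed first-return
  # counts per 1000 invited donors
  female: {dropout_prob: 0.098, other_deferral_prob: 0.054324}
  male: {dropout_prob: 0.066, other_deferral_prob: 0.039615}
  delay: {assumed: true, mean_weeks: 2, cap_weeks: 36}
  onsite_error: {assumed: true, sigma_m: 4.0, c: 1.5}
  hemocue_over_prob: 0.1

thresholds:
  female: {donation: 125.0, severe_low: 115.0}
  male: {donation: 135.0, severe_low: 125.0}

deferral:
  low_hb_weeks: 12
  low_hb_severe_weeks: 52
  other_weeks: 4

strategies:
  interval_cap_weeks: 52
  max_invitations_per_year: {A: 4, personalized: 6}

costs:
  onsite_test: 1.08
  offsite_test: 0.79
  donation: 26.49
  deferral_low_hb: 9.21
  deferral_other: 0.97

horizon_days: 365

bootstrap:
  draws: 1000
  size: 1000
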