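---
title: "Simulating personalized blood-donor recall: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating personalized blood-donor recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(donorecall)
```

## What the simulation models

A whole-blood donor makes an index donation at day 0. Their hemoglobin,
measured accurately by a hematology analyzer on the donated blood, then
recovers over the following weeks. A recall policy decides when to invite
them back; the donor may lapse, attend after some delay, be deferred for a
non-hemoglobin reason, be screened on site (under some policies), and donate
or be deferred for low hemoglobin. `run_population()` advances every donor
through this cycle for one year (365 days, integer-day clock, all events on
a weekly grid) and records an event log that `summary()` turns into per-1000
outcome counts, donations per adverse event, mean cost per donation, and the
distribution of invited intervals over reporting bands.

An *adverse event* is an inappropriate bleed (a completed donation from a
donor whose true hemoglobin is below the regulatory threshold: 125 g/L
women, 135 g/L men) or a low-hemoglobin deferral. Under the pure
post-donation strategies there is no on-site screen, so low-hemoglobin
deferrals are structurally impossible and every under-threshold attendee
bleeds; under on-site screening, measurement error decides which
under-threshold attendees bleed and which are deferred.

## The recovery model

For donor $i$, $t$ weeks after a donation with analyzer hemoglobin $h$:

$$\mu_i(t) = \beta_0 + \beta_h h + \beta_{\mathrm{age}}(a_i - 45)
  + \gamma_{\mathrm{eth}(i)} + \gamma_{\mathrm{bg}(i)} + \beta_t t,$$

with a persistent donor-level offset $b_i \sim N(0, \sigma_b^2)$ and visit
noise $e \sim N(0, \sigma_e^2)$. Linearity in $t$ with a common slope is the
deliberate simplification that a two-measurement-per-donor design forces:
with at most one observed return per donor, donor-specific slopes are not
identifiable. The model is fit and applied separately by sex.

The policy cannot observe $b_i$ — the blood service knows only the last
analyzer measurement and the donor's covariates — so the policy-facing
probability of being over threshold $c$ marginalizes over both noise terms:

$$P(\mathrm{Hb}_i(t) \ge c) =
  \Phi\!\left(\frac{\mu_i(t) - c}{\sqrt{\sigma_b^2 + \sigma_e^2}}\right).$$

The personalized interval is the smallest whole week at which this reaches
the strategy's certainty level $p_{\min}$, floored at the policy minimum and
capped at 52 weeks. It is solved in closed form by inverting the linear
predictor at the normal quantile and rounding up; a property test checks the
closed form against an exhaustive week-by-week scan. Donors who never reach
$p_{\min}$ by the cap (non-positive margin and slope, or a very low anchor)
are invited *at* the cap and flagged — inviting them eventually, rather than
never, mirrors how a blood service would treat a donor who cannot be
certified recovered. After every simulated donation the realized analyzer
value becomes the new anchor $h$ for the next cycle, so trajectories
compound: donors recalled early donate from lower anchors, and their
subsequent intervals stretch.

Whole weeks are used for intervals (reports band intervals in weeks) while
the simulation clock runs in days (1 week = 7 days); attendance delays are
drawn in whole weeks, so all event times fall on the weekly grid.

## Strategies and re-invitation rules

* **A** — fixed recall at 16 (women) / 12 (men) weeks, on-site screening at
  every attendance, at most 4 invitations per year.
* **B / C** — post-donation testing at 70% / 90% certainty, same floors, no
  on-site test.
* **D** — 90% certainty with floors lowered to 12 / 8 weeks (early recall
  for donors with high anchors or fast predicted recovery).
* **E** — recall at 70% certainty; donors whose modeled probability lies in
  $[0.7, 0.9)$ get a portable on-site test.

Personalized strategies are capped at 6 invitations per year. Low-hemoglobin
deferral re-invites after 12 weeks, or 52 weeks when the measured value is
very low (< 115 g/L women / < 125 g/L men); other deferrals re-invite after
4 weeks. After a deferral the fixed deferral interval applies verbatim and
normal strategy logic resumes at the next donation. A deferred donor keeps
their previous anchor (no donation happened), with elapsed time continuing
to accrue.

Two points were genuinely open and are resolved as package design choices,
both configurable:

* **Strategy E's band membership** is evaluated at the actual attendance
  time, not the invited time, because the on-site decision happens in
  session and attendance delay changes the modeled probability
  (`requires_onsite_test(at = "invitation")` gives the frozen alternative).
  A donor capped at 52 weeks can attend with probability still below 0.7;
  the band is half-open on both readings, so such donors are not tested.
* **Strategy A's yearly cap** counts invitations issued (not completed
  donations), including post-deferral re-invitations.

## The on-site test error model

On-site screening (gravimetry followed by spectrophotometry under the
current strategy; portable spectrophotometry under strategy E) always passes
donors whose true hemoglobin is at or over the threshold. An under-threshold
donor with deficit $d$ g/L passes — an inappropriate bleed — with
probability $\pi(d) = \mathrm{logit}^{-1}(c - d/\sigma_m)$, non-increasing
in the deficit. Defaults $\sigma_m = 4$ g/L, $c = 1.5$ give
$\pi(0) \approx 0.82$, $\pi(8) \approx 0.38$: most marginal donors pass,
deeply low donors rarely do, splitting under-threshold attendees roughly
60/40 between bleeds and deferrals under the fixed-recall strategy, in line
with the relative magnitudes reported for the pre-2018 English screening
pathway. Setting $c = -\infty$ gives a perfect test.

## The synthetic population and its calibration

The generator emulates a returning-donor cohort: sex-specific index
hemoglobin (normal, truncated below 100 g/L), age (rounded normal, 18–70),
ethnicity and ABO/RhD blood-group frequencies typical of an English donor
panel, a latent recovery offset per donor, per-invitation dropout,
per-attendance non-hemoglobin deferral, and a geometric attendance delay
(mean 2 weeks, capped at 36). Working cohorts are drawn from the reference
population with replacement, copying rows whole so the joint covariate
structure survives resampling.

Parameter defaults fall into three tiers:

* **Policy constants** (thresholds, floors, certainty levels, deferral
  intervals, caps, unit costs) are fixed by published policy and are not
  tuning knobs.
* **Behavioral rates** are calibrated to observed first-return counts per
  1000 invited donors: dropout 0.098 (women) / 0.066 (men) per invitation;
  other deferral 49/902 (women) / 37/934 (men) per attendance, applied
  identically at every recall because the informing data cover first returns
  only and give no visit-order signal.
* **Recovery-model coefficients** are assumptions, not estimates from donor
  microdata (the informing study's coefficients are not published). They
  were chosen once so the simulated cohort lands in the qualitative regime
  the real cohort exhibits — a large majority of donors recalled at the
  policy floor even under the 90%-certainty rule, with a high-risk minority
  accounting for most adverse events — which requires the anchor
  measurement to explain most of the between-donor variance:
  $\beta_h = 0.85$, $\sigma_b = 3.5$, $\sigma_e = 4.5$ g/L,
  $\beta_t = 0.3$ g/L/week, and intercepts (16.3 women, 17.75 men) placing
  the mean true hemoglobin at the current-policy floor about 10 g/L above
  the threshold. In this regime the characteristic strategy ordering
  emerges from the mechanics rather than being imposed: high certainty
  without early recall maximizes donations per adverse event, early recall
  maximizes total donations, and the pure post-donation strategies share a
  single mean cost per donation.

Every default lives in `inst/extdata/defaults.yaml`, with assumed values
labeled `assumed: true`; any subset can be overridden by a user YAML file
passed to `read_config()` or the drivers.

What the generator does **not** emulate: seasonal and venue effects,
informative observation (donors whose hemoglobin is low returning later or
not at all), donor-specific recovery slopes, ferritin/iron stores, new
donors, and behavioral responses to policy change. Passing tests therefore
show that the machinery is correct and that the qualitative strategy
comparison is robust in a plausibly calibrated synthetic world — not that
the absolute event counts transfer to any real cohort.

## Fitting and uncertainty

`fit_recovery_model()` supports both designs the two-visit data structure
admits. With one return per donor (the default generator output) it fits
per-sex OLS with the index hemoglobin as a covariate; $\sigma_b$ and
$\sigma_e$ are then not separately identifiable, so the fit reports the
total predictive sd as `residual_sd` with `latent_sd = 0` — marginal
predictions, and hence every policy computation, are unchanged by this
convention. With repeated returns per donor it fits a donor-level
random-intercept model via `lme4::lmer()` (REML) and separates the two
components. Rank-deficient designs error, naming the collinear terms.
Parameter-recovery tests check both paths against known generating values
at $n = 5000$ (within 3 SE) and exactly on noiseless data.

`bootstrap_uncertainty()` propagates parameter uncertainty: per draw it
perturbs coefficients on the natural scale (normal), sds log-normally
(cv-parameterized), and behavioral probabilities logit-normally, rescales
the cohort's latent offsets when $\sigma_b$ changes, resamples the cohort,
simulates, and summarizes; point estimates are medians with 2.5/97.5
percentile intervals. The reported design is 1000 draws of 1000 donors;
missing standard errors fall back to fixed parameters with a warning, so
intervals then reflect Monte-Carlo variation only.

## Numerical and reproducibility choices

* Money is held in integer pence; totals are exact sums and reported in GBP
  to 2 d.p. Ratios are reported to 1 d.p. and validation percent
  differences to the nearest integer.
* Every donor receives an independent RNG substream derived from the master
  seed and the donor's row position, so a donor's trajectory is invariant
  to cohort size and composition; duplicated donors in a resampled cohort
  evolve independently while sharing biology (covariates and latent
  offset). Full runs are byte-identical for a fixed seed.
* Invitations issued before day 365 are simulated even when attendance
  falls later (flagged `after_horizon`); with `carry_over = FALSE` such
  visits are recorded as `pending` instead. Interval-band tables count only
  post-donation recall invitations, excluding post-deferral re-invites.
* Degenerate inputs have defined behavior: zero predictive sd makes the
  over-threshold probability a step function; zero donations yield `NA`
  cost-per-donation and ratio sentinels; an empty reference population is
  an error.
* Interval solving uses `ceiling(t - 10^-9)` so donors exactly on a weekly
  boundary are not pushed a week late by floating-point noise.

## Problem sizes

The test suite exercises cohorts up to 10,000 donors per strategy and sex
(about two minutes in total), with smaller cohorts (hundreds to a few
thousand) for distributional and property checks, 5000-donor
parameter-recovery fits, and reduced bootstrap designs (tens of draws of
~100 donors, with 30 meta-replicates for the coverage check). The
acceptance script simulates 10,000 donors per strategy and sex plus the
first-return validation, completing in under a minute on one CPU. These
sizes keep Monte-Carlo error well inside the tested tolerances; all scale
linearly in donors.

## Known limitations

The linear common-slope recovery model understates heterogeneity at the
extremes, which is exactly where adverse events concentrate — the
first-return validation under-predicts under-threshold donations while
matching attendance, dropout and deferral counts closely, the expected
signature of thin tails. Dropout and deferral rates are visit-order
constant; real lapse rates depend on deferral history. The cost model is
blood-service-only (no donor time, travel, or downstream donor-health
costs). None of the absolute quantities should be read as estimates for a
real service without refitting the recovery model and behavior parameters
to that service's data via `fit_recovery_model()` and the config file.
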