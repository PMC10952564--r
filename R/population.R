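#' Configuration for the synthetic donor population generator
#'
#' Describes a returning-donor cohort: sex mix, sex-specific index hemoglobin
#' distributions (the accurate analyzer measurement at the index donation),
#' covariate category frequencies, and the between-donor random-intercept sd
#' used to realize each donor's latent offset. Defaults are plausible values
#' for an English returning whole-blood donor population and are assumptions,
#' not estimates from any donor dataset; every element can be overridden.
#'
#' @param n number of donors to generate.
#' @param sex_mix named numeric, proportions for `female` and `male`; must sum
#'   to 1.
#' @param index_hb list with elements `female` and `male`, each `c(mean, sd)`
#'   in g/L for the index hemoglobin normal distribution.
#' @param index_hb_floor lower truncation for index hemoglobin, g/L. Donors
#'   below the analyzer floor would not be in a returning-donor cohort.
#' @param age_mean,age_sd,age_range parameters of the (rounded, clipped)
#'   normal age distribution in years.
#' @param ethnicity_freq named numeric of category frequencies, must sum to 1.
#' @param blood_group_freq named numeric of ABO/RhD category frequencies,
#'   must sum to 1.
#' @param latent_sd between-donor random-intercept sd in g/L; each donor's
#'   `latent_offset` is drawn from N(0, latent_sd).
#' @return an object of class `population_config`.
#' @seealso [generate_reference_population()]
#' @export
population_config <- function(n = 10000,
                              sex_mix = c(female = 0.5, male = 0.5),
                              index_hb = list(female = c(mean = 134, sd = 10),
                                              male   = c(mean = 149, sd = 11)),
                              index_hb_floor = 100,
                              age_mean = 45, age_sd = 13,
                              age_range = c(18, 70),
                              ethnicity_freq = c(White = 0.88, Asian = 0.05,
                                                 Black = 0.04,
                                                 MixedOther = 0.03),
                              blood_group_freq = c(`O+` = 0.35, `O-` = 0.13,
                                                   `A+` = 0.30, `A-` = 0.08,
                                                   `B+` = 0.08, `B-` = 0.02,
                                                   `AB+` = 0.03,
                                                   `AB-` = 0.01),
                              latent_sd = 3.5) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n))
    stopf("n must be a single non-negative integer")
  for (nm in c("sex_mix", "ethnicity_freq", "blood_group_freq")) {
    f <- get(nm)
    check_prob(f, nm)
    if (abs(sum(f) - 1) > 1e-8)
      stopf("%s frequencies must sum to 1 (got %.6f)", nm, sum(f))
    if (is.null(names(f)) || any(names(f) == ""))
      stopf("%s must be a named vector", nm)
  }
  for (s in c("female", "male")) {
    p <- index_hb[[s]]
    if (is.null(p) || length(p) != 2L || p[2] <= 0)
      stopf("index_hb$%s must be c(mean, sd) with sd > 0", s)
  }
  if (latent_sd < 0) stopf("latent_sd must be non-negative")
  if (age_range[1] < 18) stopf("donors must be 18 or older")
  structure(list(n = as.integer(n), sex_mix = sex_mix, index_hb = index_hb,
                 index_hb_floor = index_hb_floor, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 ethnicity_freq = ethnicity_freq,
                 blood_group_freq = blood_group_freq,
                 latent_sd = latent_sd),
            class = "population_config")
}

#' Generate a synthetic reference donor population
#'
#' Draws `n` returning donors with independent covariates (age, ethnicity,
#' ABO/RhD blood group), sex-specific index hemoglobin truncated below at the
#' configured floor, and a hidden donor-level latent offset realizing
#' between-donor heterogeneity in hemoglobin recovery. The population stands
#' in for a real returning-donor cohort so every downstream stage can run
#' without external data.
#'
#' @param config a [population_config()].
#' @param seed integer seed; the draw is fully reproducible given the seed.
#' @param sex optionally restrict to `"female"` or `"male"` (single-sex
#'   cohorts are simulated separately, as the recovery model is sex-stratified).
#' @return a `donor_population`: a data.frame with columns `id`, `sex`, `age`,
#'   `ethnicity`, `blood_group`, `index_hb`, `latent_offset`, carrying the
#'   config and seed as attributes.
#' @examples
#' pop <- generate_reference_population(population_config(n = 100), seed = 1)
#' table(pop$sex)
#' @export
generate_reference_population <- function(config, seed, sex = NULL) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n
  out <- data.frame(id = integer(0), sex = character(0), age = numeric(0),
                    ethnicity = character(0), blood_group = character(0),
                    index_hb = numeric(0), latent_offset = numeric(0),
                    stringsAsFactors = FALSE)
  if (n > 0L) {
    rs <- .restore_rng()
    on.exit(rs(), add = TRUE)
    set.seed(as.integer(seed %% .SEED_MOD))
    sexes <- if (is.null(sex)) {
      sample(names(config$sex_mix), n, replace = TRUE, prob = config$sex_mix)
    } else {
      match.arg(sex, c("female", "male"))
      rep(sex, n)
    }
    age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                     config$age_range[1]), config$age_range[2])
    eth <- sample(names(config$ethnicity_freq), n, replace = TRUE,
                  prob = config$ethnicity_freq)
    bg <- sample(names(config$blood_group_freq), n, replace = TRUE,
                 prob = config$blood_group_freq)
    hb <- numeric(n)
    for (s in c("female", "male")) {
      i <- sexes == s
      if (any(i)) {
        p <- config$index_hb[[s]]
        hb[i] <- .rnorm_trunc_low(sum(i), p[[1]], p[[2]], config$index_hb_floor)
      }
    }
    lat <- if (config$latent_sd > 0) stats::rnorm(n, 0, config$latent_sd)
           else numeric(n)
    out <- data.frame(id = seq_len(n), sex = sexes, age = age, ethnicity = eth,
                      blood_group = bg, index_hb = hb, latent_offset = lat,
                      stringsAsFactors = FALSE)
  }
  structure(out, config = config, seed = seed,
            class = c("donor_population", "data.frame"))
}

# Normal truncated below at `lo` by rejection; vectorized, exact.
.rnorm_trunc_low <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo]
  }
  x
}

# Save/restore the caller's RNG state so generators are self-contained.
.restore_rng <- function() {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Resample a donor cohort with replacement
#'
#' Draws `m` donors with replacement from a reference population, copying rows
#' whole so the joint covariate structure (correlation between age, blood
#' group, ethnicity and index hemoglobin) is retained in the simulated cohort.
#'
#' @param reference a `donor_population` (or data.frame of donors), non-empty.
#' @param m number of donors to draw.
#' @param seed integer seed.
#' @return a `donor_population` of `m` rows; every row is an exact copy of a
#'   reference row (ids included).
#' @export
resample_population <- function(reference, m, seed) {
  if (nrow(reference) == 0L) stopf("reference population is empty")
  rs <- .restore_rng()
  on.exit(rs(), add = TRUE)
  set.seed(as.integer(seed %% .SEED_MOD))
  idx <- sample.int(nrow(reference), m, replace = TRUE)
  out <- reference[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, config = attr(reference, "config"), seed = seed,
            class = c("donor_population", "data.frame"))
}

#' @export
#' @method print donor_population
print.donor_population <- function(x, ...) {
  cat(sprintf("Donor population: %d donors (%d women, %d men)\n", nrow(x),
              sum(x$sex == "female"), sum(x$sex == "male")))
  if (nrow(x)) {
    cat(sprintf("  index Hb g/L: mean %.1f (sd %.1f)\n",
                mean(x$index_hb), stats::sd(x$index_hb)))
    print(utils::head(as.data.frame(x), 5))
    if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Generate a two-visit longitudinal dataset from a recovery model
#'
#' Produces one index and one return hemoglobin per donor: the return value is
#' the recovery-model linear predictor at the donor's return time plus the
#' donor's latent offset and residual noise. Used as a fixture generator for
#' parameter-recovery testing of [fit_recovery_model()].
#'
#' @param model a [recovery_model()] for the donors' sex stratum.
#' @param donors a `donor_population` (single sex, matching the model).
#' @param return_times numeric vector of weeks since the index donation, one
#'   per donor (recycled if length 1); all must be non-negative.
#' @param seed integer seed for the residual draws.
#' @return data.frame with columns `id`, `sex`, `age`, `ethnicity`,
#'   `blood_group`, `index_hb`, `t_weeks`, `return_hb`.
#' @export
generate_two_visit_dataset <- function(model, donors, return_times, seed) {
  stopifnot(inherits(model, "recovery_model"))
  if (any(return_times < 0)) stopf("return_times must be non-negative")
  t <- rep_len(return_times, nrow(donors))
  rs <- .restore_rng()
  on.exit(rs(), add = TRUE)
  set.seed(as.integer(seed %% .SEED_MOD))
  mu <- linear_predictor(model, donors, t)
  eps <- if (model$residual_sd > 0)
    stats::rnorm(nrow(donors), 0, model$residual_sd) else numeric(nrow(donors))
  data.frame(id = donors$id, sex = donors$sex, age = donors$age,
             ethnicity = donors$ethnicity, blood_group = donors$blood_group,
             index_hb = donors$index_hb, t_weeks = t,
             return_hb = mu + donors$latent_offset + eps,
             stringsAsFactors = FALSE)
}

#' Read or write a donor table
#'
#' CSV interchange format with header
#' `id,sex,age,ethnicity,blood_group,index_hb`. The hidden `latent_offset` is
#' never serialized: it is unobservable state, regenerated from a seed on read.
#'
#' @param donors a `donor_population`.
#' @param path file path.
#' @param latent_sd sd used to regenerate latent offsets on read (g/L).
#' @param seed seed for the regenerated offsets.
#' @return `read_donors` returns a `donor_population`; `write_donors` returns
#'   the path invisibly.
#' @export
write_donors <- function(donors, path) {
  utils::write.csv(
    as.data.frame(donors)[c("id", "sex", "age", "ethnicity", "blood_group",
                            "index_hb")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_donors
#' @export
read_donors <- function(path, latent_sd = 3.5, seed = 1) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "ethnicity", "blood_group", "index_hb")
  if (!all(need %in% names(d)))
    stopf("donor CSV must have columns %s", paste(need, collapse = ", "))
  if (any(d$index_hb <= 0)) stopf("index_hb must be positive")
  if (any(d$age < 18)) stopf("donors must be 18 or older")
  rs <- .restore_rng()
  on.exit(rs(), add = TRUE)
  set.seed(as.integer(seed %% .SEED_MOD))
  d$latent_offset <- if (latent_sd > 0) stats::rnorm(nrow(d), 0, latent_sd)
                     else numeric(nrow(d))
  structure(d, seed = seed, class = c("donor_population", "data.frame"))
}
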