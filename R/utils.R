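#' @keywords internal
"_PACKAGE"

# Mersenne prime modulus for per-donor substreams; keeps derived seeds in
# [1, 2^31 - 2] so set.seed() always accepts them.
.SEED_MOD <- 2147483647

#' Derive independent per-donor RNG seeds from a master seed
#'
#' Each simulated donor gets an RNG substream keyed on the master seed and the
#' donor's row position in the population, so trajectories do not depend on
#' population size or on which other donors are present.
#'
#' @param seed master integer seed.
#' @param n number of substreams.
#' @return integer vector of length `n`, each usable with [set.seed()].
#' @keywords internal
donor_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  s0 <- as.numeric(seed %% .SEED_MOD)
  # Lehmer-style scramble; distinct rows give distinct seeds within a run.
  as.integer((s0 * 48271 + 16807 * seq_len(n)) %% (.SEED_MOD - 1) + 1)
}

#' Convert pounds to integer pence
#' @param gbp numeric amount in GBP.
#' @return integer pence (exact money arithmetic).
#' @keywords internal
to_pence <- function(gbp) as.integer(round(gbp * 100))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("%s must be a probability in [0, 1]", what)
  invisible(x)
}
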