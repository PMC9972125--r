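#' Derive independent child seeds from a root seed
#'
#' Reproducibility across nested layers of randomness (replications within a
#' simulation condition, resamples within a bootstrap, chains within a
#' sampler) uses a single documented spawning rule: under `set.seed(seed)`,
#' `n` integers are drawn without replacement from `1:(2^31 - 2)`. Every
#' derived seed is therefore itself a valid 32-bit seed, and any unit of work
#' can be re-run in isolation from its own child seed.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds to spawn.
#' @return An integer vector of length `n`.
#' @examples
#' spawn_seeds(1, 3)
#' @export
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Run code under a seed when one is given; otherwise use the ambient RNG
# stream (so seed = NULL composes with an outer set.seed()).
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
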