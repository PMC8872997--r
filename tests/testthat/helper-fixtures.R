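# Shared small fixtures, built once per test run.

# moderate cohort with default (study-shaped) parameters
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(n_individuals = 1200, seed = 101))
    }
    cache
  }
})

# strong planted signal for recovery checks
fixture_cohort_strong <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        n_individuals = 4000, canonical_r_a = 0.25, canonical_r_b = 0.2,
        seed = 202
      ))
    }
    cache
  }
})

# random AI-like matrix + score with no structure
random_instance <- function(n, p, seed) {
  withr::with_seed(seed, {
    list(X = matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("r", seq_len(p)))),
         y = rnorm(n))
  })
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
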