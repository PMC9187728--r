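# Shared fixtures, all generated in code at test time.

# Reduced factorial design: 3 x 6 x 3 = 54 condition groups.
small_design <- function(replicates = 3) {
  pn_design(temperatures = c(18, 24, 30),
            ppfd_levels = c(1600, 800, 400, 100, 30, 0),
            blue_ratios = c(0.1, 0.5, 0.9),
            replicates = replicates)
}

# Condition-level split on the reduced design, ready for model fitting.
small_split <- function(seed = 1, noise_sd = 0.1) {
  data <- simulate_gas_exchange(small_design(),
                                pn_truth_params(noise_sd = noise_sd,
                                                seed = seed))
  split_groups(clean_replicates(data), seed = seed)
}

# Uniform random condition-level tibble (distinct inputs almost surely).
random_conditions <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    temperature = runif(n, 18, 30),
    ppfd = runif(n, 0, 1600),
    blue_ratio = runif(n, 0.1, 0.9),
    pn = runif(n, -1.5, 18)
  ))
}

expect_unit_norm <- function(pop, tol = 1e-12) {
  expect_lt(max(abs(pop$alpha^2 + pop$beta^2 - 1)), tol)
}
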