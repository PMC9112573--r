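# Shared fixtures. Everything is generated in code at test time; MLP widths
# and epoch counts are explicitly configured down so the suite exercises the
# full protocol at desk scale.

tiny_mlp <- function(hidden = c(16L, 16L), epochs = 20L, batch_size = 128L) {
  mlp_control(hidden = hidden, epochs = epochs, batch_size = batch_size)
}

# A small schema with no spline terms, for exact linear-algebra checks.
toy_schema <- function() {
  tibble::tibble(
    name = c("x1", "x2", "b1"),
    kind = c("continuous", "continuous", "binary"),
    levels = vector("list", 3L),
    spline = c(FALSE, FALSE, FALSE)
  )
}

toy_linear_data <- function(n = 200, seed = 1, binary = FALSE) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = runif(n, -2, 2), b1 = rbinom(n, 1, 0.4)
    )
    eta <- 0.5 + 1.2 * d$x1 - 0.7 * d$x2 + 0.9 * d$b1
    if (binary) {
      d$y <- rbinom(n, 1, plogis(eta))
    } else {
      d$y <- eta + rnorm(n, 0, 0.5)
    }
    d
  })
}

# Complete synthetic cohort (no missingness) with oracle truth.
complete_cohort <- function(n, seed = 1, ...) {
  generate_cohort(generator_config(n = n, seed = seed, ...))
}

# Small imputed stack + OOB store on the binary task, reused across tests.
small_binary_store <- function(n = 300, m = 2, B = 3, seed = 5, ...) {
  sim <- simulate_cohort(generator_config(n = n, seed = seed))
  stack <- impute_cohort(sim$cohort, m = m, seed = seed, cycles = 2)
  elig <- outcome_availability_mask(stack$datasets[[1]], "binary")
  plans <- make_bootstrap_plans(length(elig), m, B, seed = seed)
  store <- generate_oob_predictions(
    stack, plans, "binary", mlp_control = tiny_mlp(epochs = 8),
    ridge_lambda = 1, keep_models = 3, seed = seed, ...)
  list(sim = sim, stack = stack, plans = plans, store = store)
}
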