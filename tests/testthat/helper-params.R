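# Shared fixtures built in code: variants of the default parameter set used
# across test files.

base_params <- default_params()

# No deaths at all: cohort is conserved in the living states.
immortal_params <- function(params = base_params) {
  for (arm in strategy_names(params)) {
    params <- param_set(params, paste0("cv_death.", arm), 0)
  }
  params$noncv_mortality$prob[] <- 0
  params
}

# No events either: pure state-transition dynamics.
eventless_params <- function(params = immortal_params()) {
  for (arm in strategy_names(params)) {
    params <- param_set(params, paste0("hf_hospitalization.", arm), 0)
  }
  params
}

# Everyone starts in NYHA2 and stays: utility arithmetic becomes exact.
nyha2_forever_params <- function(params = eventless_params()) {
  params$settings$initial_distribution <- c(0, 1, 0, 0)
  params$nyha_matrix[] <- 0
  diag(params$nyha_matrix) <- 1
  params
}

expect_rows_stochastic <- function(m, tol = 1e-12) {
  expect_true(all(abs(rowSums(m) - 1) <= tol))
  expect_true(all(m >= 0 & m <= 1))
}
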