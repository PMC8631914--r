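test_that("simulated trajectories are reproducible and respect the state law", {
  a <- simulate_cohort(base_params, "dapagliflozin", 50, seed = 9)
  b <- simulate_cohort(base_params, "dapagliflozin", 50, seed = 9)
  expect_identical(a$states, b$states)
  expect_identical(a$hospitalized, b$hospitalized)

  one <- simulate_cohort(base_params, "control1", 1, seed = 4)
  expect_equal(dim(one$states), c(1, 41))

  # absorbing death: no transitions out, no events after death
  sim <- simulate_cohort(base_params, "control2", 400, seed = 2)
  for (k in 1:40) {
    dead <- sim$states[, k] >= 5
    expect_true(all(sim$states[dead, k + 1] == sim$states[dead, k]))
    expect_false(any(sim$hospitalized[dead, k]))
  }
  # readmission implies hospitalization in the same cycle
  expect_true(all(sim$hospitalized[sim$readmitted]))

  # certain death: everyone dead after the first cycle
  p1 <- param_set(base_params, "cv_death.dapagliflozin", 1)
  p1$noncv_mortality$prob[] <- 0
  sim1 <- simulate_cohort(p1, "dapagliflozin", 100, seed = 1)
  expect_true(all(sim1$states[, 2] == 5))

  # empirical occupancy sums to one per cycle with binomial SEs
  occ <- sim$occupancy
  sums <- tapply(occ$fraction, occ$cycle, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(occ$se <= sqrt(0.25 / 400) + 1e-12))
})

test_that("empirical transition frequencies match the cycle matrices", {
  # chi-square goodness of fit of observed first-cycle transitions from NYHA2
  # against the constructed matrix row
  n <- 50000
  sim <- simulate_cohort(base_params, "dapagliflozin", n, seed = 31)
  sp <- strategy_params(base_params, "dapagliflozin")
  m <- build_cycle_matrix(sp, base_params$nyha_matrix, base_params, 66)
  from2 <- sim$states[, 1] == 2
  obs <- tabulate(sim$states[from2, 2], nbins = 6)
  keep <- m["NYHA2", ] > 0
  gof <- suppressWarnings(
    stats::chisq.test(obs[keep], p = m["NYHA2", keep] / sum(m["NYHA2", keep]))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("the cohort engine agrees with the microsimulation oracle", {
  n <- 40000
  sim <- simulate_cohort(base_params, "control1", n, seed = 17)
  tr <- run_cohort(base_params, "control1")

  # terminal occupancy within 3 binomial SEs for every state
  emp <- sim$occupancy[sim$occupancy$cycle == 40, ]
  expected <- unlist(tr[40, paste0("end_", emp$state)])
  se <- pmax(emp$se, sqrt(0.5 / n)) # guard against zero-SE cells
  expect_true(all(abs(emp$fraction - expected) <= 3 * se))

  # cumulative event counts within 3 SEs
  tot_hosp <- sum(sim$events$hospitalizations) / n
  exp_hosp <- sum(tr$hospitalizations)
  se_hosp <- stats::sd(rowSums(sim$hospitalized)) / sqrt(n)
  expect_lt(abs(tot_hosp - exp_hosp), 3 * se_hosp)

  # per-patient discounted cost/QALY means within 3 SEs of the cohort totals
  ms <- microsim_cea(sim, base_params)
  cohort <- cea_accumulate(tr, base_params)
  expect_lt(abs(ms$mean_cost - cohort$total_cost), 3 * ms$se_cost)
  expect_lt(abs(ms$mean_qaly - cohort$total_qaly), 3 * ms$se_qaly)
})

test_that("per-patient accumulation matches exact arithmetic in a degenerate cohort", {
  p <- nyha2_forever_params()
  p$settings$annual_discount <- 0
  sim <- simulate_cohort(p, "control1", 10, seed = 8, horizon = 1)
  res <- microsim_cea(sim, p)
  expect_equal(res$mean_qaly, 0.72)
  expect_equal(res$se_qaly, 0)

  pz <- p
  pz$costs[] <- 0
  simz <- simulate_cohort(pz, "control1", 10, seed = 8, horizon = 1)
  expect_equal(microsim_cea(simz, pz)$mean_cost, 0)
})

test_that("synthetic trials recover the per-cycle probability they were built from", {
  zero <- synthesize_trial(0, 18, 1000, seed = 1)
  expect_equal(zero$event_proportion, 0)
  expect_equal(prob_per_cycle(zero$event_proportion, zero$followup_months), 0)

  sat <- synthesize_trial(0.95, 60, 1000, seed = 1)
  expect_gt(sat$event_proportion, 0.99)

  # follow-up rounds to whole cycles: 18.2 months -> 18
  tt <- synthesize_trial(0.0165, 18.2, 2000, seed = 6)
  expect_equal(tt$followup_months, 18)

  n <- 100000
  tr <- synthesize_trial(0.01650, 18.2, n, seed = 13)
  recovered <- prob_per_cycle(tr$event_proportion, tr$followup_months)
  # delta-method SE of the recovered per-cycle probability
  prop <- tr$event_proportion
  se_prop <- sqrt(prop * (1 - prop) / n)
  ncyc <- tr$followup_months / 3
  deriv <- (1 - recovered) / (ncyc * (1 - prop))
  expect_lt(abs(recovered - 0.01650), 3 * deriv * se_prop)
})

test_that("histories export in long format with consistent flags", {
  sim <- simulate_cohort(base_params, "empagliflozin", 5, seed = 3, horizon = 1)
  h <- microsim_histories(sim)
  expect_equal(nrow(h), 5 * 5)
  expect_true(all(h$state %in% c(
    "NYHA1", "NYHA2", "NYHA3", "NYHA4", "DEAD_CV", "DEAD_NONCV"
  )))
  expect_true(all(h$hospitalized[h$readmitted]))
  expect_false(any(h$hospitalized[h$cycle == 0]))
})
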