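test_that("cycle matrices apply competing mortality then NYHA redistribution", {
  p <- base_params
  sp <- strategy_params(p, "dapagliflozin")

  # no-mortality limit: the NYHA block is the transition matrix itself
  p0 <- eventless_params()
  m0 <- build_cycle_matrix(strategy_params(p0, "control1"), p0$nyha_matrix, p0, 66)
  expect_equal(m0[1:4, 1:4], p0$nyha_matrix)
  expect_rows_stochastic(m0)

  # certain-death limit
  p1 <- param_set(p, "cv_death.dapagliflozin", 1)
  p1$noncv_mortality$prob[] <- 0
  m1 <- build_cycle_matrix(
    strategy_params(p1, "dapagliflozin"), p1$nyha_matrix, p1, 66
  )
  expect_equal(unname(m1[1:4, "DEAD_CV"]), rep(1, 4))
  expect_equal(max(m1[1:4, 1:4]), 0)

  # hand-computed row at the default inputs, age 66:
  # survivors (1 - 0.01650 - 0.00243) redistributed over (0.008, 0.981,
  # 0.010, 0.001), plus the two death entries
  m <- build_cycle_matrix(sp, p$nyha_matrix, p, 66)
  expect_equal(
    unname(m["NYHA2", ]),
    c(0.00784856, 0.96242967, 0.0098107, 0.00098107, 0.01650, 0.00243),
    tolerance = 1e-12
  )
  expect_rows_stochastic(m)

  # age bands: probabilities step up at 70 and 75 and carry forward past 79
  expect_equal(m["NYHA1", "DEAD_NONCV"], 0.002430)
  m70 <- build_cycle_matrix(sp, p$nyha_matrix, p, 70)
  expect_equal(m70["NYHA1", "DEAD_NONCV"], 0.003042)
  m88 <- build_cycle_matrix(sp, p$nyha_matrix, p, 88)
  expect_equal(m88["NYHA1", "DEAD_NONCV"], 0.004185)

  # impossible parameter combination
  p2 <- param_set(p, "cv_death.control2", 0.999)
  expect_error(
    build_cycle_matrix(strategy_params(p2, "control2"), p2$nyha_matrix, p2, 66),
    "exceed 1"
  )
})

test_that("cohort traces conserve occupancy and accumulate deaths monotonically", {
  for (arm in strategy_names(base_params)) {
    tr <- run_cohort(base_params, arm)
    expect_equal(nrow(tr), 40)
    totals <- tr$end_NYHA1 + tr$end_NYHA2 + tr$end_NYHA3 + tr$end_NYHA4 +
      tr$end_DEAD_CV + tr$end_DEAD_NONCV
    expect_true(all(abs(totals - 1) <= 1e-9))
    expect_true(all(diff(tr$end_DEAD_CV) >= -1e-15))
    expect_true(all(diff(tr$end_DEAD_NONCV) >= -1e-15))
    expect_true(all(diff(survival_curve(tr)$alive) <= 1e-15))
    expect_equal(tr$readmissions, tr$hospitalizations * 0.1189)
  }
})

test_that("degenerate horizons and immortal cohorts behave exactly", {
  tr0 <- run_cohort(base_params, "dapagliflozin", horizon = 0)
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$hospitalizations, 0)
  expect_equal(
    unname(unlist(tr0[, paste0("start_", c("NYHA2", "NYHA3", "NYHA4"))])),
    c(0.713, 0.28, 0.007)
  )

  tr <- run_cohort(immortal_params(), "dapagliflozin")
  expect_true(all(abs(tr$alive_end - 1) <= 1e-12))
  expect_equal(survival_curve(tr)$alive, rep(1, 41))
  expect_error(run_cohort(base_params, "nobody"), "unknown strategy")
})

test_that("median survival reports the crossing bracket on the cycle grid", {
  tr <- run_cohort(immortal_params(), "dapagliflozin")
  ms <- median_survival(tr)
  expect_true(ms$censored)
  expect_true(is.na(ms$median))

  # the default cohort crosses 0.5 between consecutive boundaries; the point
  # estimate is the bracket's lower endpoint, the alternative convention its
  # upper endpoint
  trd <- run_cohort(base_params, "dapagliflozin")
  msd <- median_survival(trd)
  sc <- survival_curve(trd)
  expect_gt(sc$alive[sc$time == msd$bracket_lower], 0.5)
  expect_lte(sc$alive[sc$time == msd$bracket_upper], 0.5)
  expect_equal(msd$bracket_upper - msd$bracket_lower, 0.25)
  expect_equal(
    median_survival(trd, convention = "first_at_or_below")$median,
    msd$bracket_upper
  )

  # immediate crossing: first boundary at or below 0.5 is the first cycle end
  pfast <- param_set(base_params, "cv_death.dapagliflozin", 0.6)
  trf <- run_cohort(pfast, "dapagliflozin")
  expect_equal(
    median_survival(trf, convention = "first_at_or_below")$median, 0.25
  )
})

test_that("cumulative event rates count deaths and hospitalization episodes", {
  expect_equal(
    unlist(cumulative_event_rates(run_cohort(base_params, "control1"), 0)),
    c(all_cause_mortality = 0, cv_mortality = 0, hf_hospitalization = 0)
  )
  quiet <- eventless_params()
  expect_equal(
    sum(cumulative_event_rates(run_cohort(quiet, "control1"), 24)), 0
  )

  tr <- run_cohort(base_params, "dapagliflozin")
  r18 <- cumulative_event_rates(tr, 18)
  expect_equal(
    r18$all_cause_mortality,
    100 * (tr$end_DEAD_CV[6] + tr$end_DEAD_NONCV[6])
  )
  expect_equal(
    r18$hf_hospitalization,
    100 * sum(tr$hospitalizations[1:6] + tr$readmissions[1:6])
  )
  expect_error(cumulative_event_rates(tr, 17), "multiple")
  expect_error(cumulative_event_rates(tr, 150), "beyond")
})

test_that("traces export as tidy CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- run_cohort(base_params, "control2", horizon = 1)
  write_trace_csv(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 4)
  expect_equal(back$strategy, rep("control2", 4))
  expect_equal(back$end_NYHA2, tr$end_NYHA2)
})
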