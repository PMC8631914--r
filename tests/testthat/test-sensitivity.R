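test_that("moment fits reproduce their target moments", {
  f <- fit_gamma(118.95, 118.95, 556.21)
  s <- (556.21 - 118.95) / (2 * 1.96)
  expect_equal(f$shape * f$scale, 118.95)
  expect_equal(f$shape * f$scale^2, s^2)

  b <- fit_beta(0.18, 0.17325, 0.18725)
  m <- b$shape1 / (b$shape1 + b$shape2)
  v <- b$shape1 * b$shape2 /
    ((b$shape1 + b$shape2)^2 * (b$shape1 + b$shape2 + 1))
  expect_equal(m, 0.18, tolerance = 1e-9)
  expect_equal(v, ((0.18725 - 0.17325) / (2 * 1.96))^2, tolerance = 1e-9)

  # the fitted 95% central interval lands back on the stated range
  lo <- qbeta(0.025, b$shape1, b$shape2)
  hi <- qbeta(0.975, b$shape1, b$shape2)
  width <- 0.18725 - 0.17325
  expect_lt(abs(lo - 0.17325), 0.1 * width)
  expect_lt(abs(hi - 0.18725), 0.1 * width)

  expect_true(fit_beta(0.5, 0.5, 0.5)$fixed)
  expect_true(fit_gamma(10, 10, 10)$fixed)
  expect_error(fit_beta(0.5, -1, 1), "variance")
  expect_equal(fit_dirichlet(c(0.1, 0.2, 0.3, 0.4), 100), c(10, 20, 30, 40))
})

test_that("tornado entries vary one parameter at a time and restore base case", {
  res <- owsa(base_params, "dapa")
  expect_s3_class(res, "hf_owsa")
  expect_equal(nrow(res), sum(is.finite(base_params$specs$low)))
  expect_false(any(res$invalid))
  # sorted by descending spread
  sp <- res$spread[is.finite(res$spread)]
  expect_true(all(diff(sp) <= 1e-9))

  # discount-rate bounds bracket the base case (more discounting, higher ICER)
  base_icer <- attr(res, "base_icer")
  disc <- res[res$path == "discount", ]
  expect_lt(disc$icer_low, base_icer)
  expect_gt(disc$icer_high, base_icer)

  # collapsing every range to the mean reproduces the base-case ICER exactly
  flat <- base_params$specs
  flat$low <- flat$mean
  flat$high <- flat$mean
  flat <- flat[is.finite(flat$low), ]
  res_flat <- owsa(base_params, "dapa", specs = flat)
  expect_true(all(abs(res_flat$icer_low - base_icer) < 1e-9))
  expect_true(all(res_flat$spread < 1e-9))

  # CV mortality bounds destroy the empagliflozin pair's cost-effectiveness:
  # at control2's low bound the pair loses its QALY gain entirely (negative
  # net benefit), and at empagliflozin's high bound the ICER blows far past
  # 1x GDP per capita
  rese <- owsa(base_params, "empa")
  row <- rese[rese$path == "cv_death.control2", ]
  expect_lt(row$nmb_low, 0)
  row2 <- rese[rese$path == "cv_death.empagliflozin", ]
  expect_gt(row2$icer_high, base_params$settings$gdp_per_capita)
})

test_that("invalid perturbations are flagged, not clamped", {
  specs <- tibble::tibble(
    path = "cv_death.dapagliflozin", mean = 0.0165,
    low = 0.0165, high = 1.5, distribution = "beta"
  )
  res <- owsa(base_params, "dapa", specs = specs)
  expect_true(res$invalid)
  expect_equal(res$verdict_high, "invalid")
  expect_true(is.finite(res$icer_low))
})

test_that("scenarios rerun the model under overrides without touching the base", {
  base <- glance(cea_compare(base_params, "dapa"))
  none <- run_scenario(base_params, list(), "dapa", label = "none")
  expect_equal(none$icer, base$icer)

  sc <- run_scenario(base_params, "horizon_20", "dapa")
  expect_equal(sc$scenario, "horizon_20")
  expect_lt(sc$icer, base$icer)
  expect_error(run_scenario(base_params, "horizon_99", "dapa"), "available")
  expect_error(
    run_scenario(base_params, list("cost.sildenafil" = 1), "dapa"),
    "unknown parameter path"
  )

  # ICER falls as hospitalization cost rises, for both pairs
  for (pair in c("dapa", "empa")) {
    icers <- purrr::map_dbl(
      paste0("hospital_", c("town", "county", "municipal", "provincial", "ministerial")),
      ~ run_scenario(base_params, .x, pair)$icer
    )
    expect_true(all(diff(icers) < 0))
  }

  # diabetes scenarios require user-supplied subgroup probabilities
  expect_error(diabetes_scenario(), "subgroup")
  ov <- diabetes_scenario(
    cv_death = c(dapagliflozin = 0.012, control1 = 0.018),
    hf_hospitalization = c(dapagliflozin = 0.014, control1 = 0.022)
  )
  dia <- run_scenario(base_params, ov, "dapa", label = "diabetes_custom")
  expect_true(is.finite(dia$icer))
})

test_that("PSA is seed-reproducible and its draws centre on the base case", {
  a <- run_psa(base_params, "dapa", n_draws = 40, seed = 11)
  b <- run_psa(base_params, "dapa", n_draws = 40, seed = 11)
  expect_equal(a$draws, b$draws)
  c <- run_psa(base_params, "dapa", n_draws = 40, seed = 12)
  expect_false(isTRUE(all.equal(a$draws$dcost, c$draws$dcost)))
  expect_equal(a$pair, c("dapagliflozin", "control1"))

  # sampled parameter means converge to the base-case means (3-SE band)
  big <- run_psa(base_params, "dapa", n_draws = 2000, seed = 5)
  specs <- base_params$specs
  for (path in c(
    "cv_death.dapagliflozin", "utility.NYHA2", "cost.hospitalization",
    "event_disutility"
  )) {
    x <- big$draws[[path]]
    target <- specs$mean[specs$path == path]
    expect_lt(abs(mean(x) - target), 3 * stats::sd(x) / sqrt(length(x)))
  }
})

test_that("degenerate PSA collapses to the base case", {
  p <- base_params
  p$specs$low <- p$specs$mean
  p$specs$high <- p$specs$mean
  p$settings$sample_nyha <- FALSE
  psa <- run_psa(p, "dapa", n_draws = 5, seed = 3)
  base <- cea_compare(p, "dapa")
  expect_true(all(abs(psa$draws$dcost - base$incremental_cost) < 1e-9))
  expect_true(all(abs(psa$draws$dqaly - base$incremental_qaly) < 1e-9))
  expect_true(probability_ce(psa) %in% c(0, 1))

  # single-point CEAC steps at dC/dE
  icer <- base$icer
  curve <- ceac(psa, wtp_grid = c(icer - 100, icer + 100))
  expect_equal(curve$probability, c(0, 1))
})

test_that("the CEAC is the pointwise NMB exceedance curve", {
  psa <- run_psa(base_params, "empa", n_draws = 100, seed = 21)
  curve <- ceac(psa, wtp_grid = c(0, 5000, 11008.07, 30000))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # at zero WTP, the fraction of cost-saving draws
  expect_equal(curve$probability[1], mean(psa$draws$dcost < 0))
  # internal consistency with probability_ce at the threshold
  expect_equal(curve$probability[3], probability_ce(psa))
  # monotone when every draw gains QALYs
  if (all(psa$draws$dqaly > 0)) {
    expect_true(all(diff(curve$probability) >= 0))
  }
})
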