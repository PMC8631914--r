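# One-way sensitivity analysis (tornado), scenario analysis, and seeded
# probabilistic sensitivity analysis with CEAC computation.

#' Method-of-moments distribution fits from a mean and a 95% range
#'
#' The stated range `(low, high)` is read as a 95% central interval, giving
#' `sd = (high - low) / (2 * 1.96)`. `fit_beta()` and `fit_gamma()` match the
#' first two moments; `fit_dirichlet()` scales a probability row by a
#' concentration parameter. A zero-width range yields a degenerate fit
#' flagged `fixed`.
#'
#' @param mean Distribution mean (in `(0, 1)` for beta, `> 0` for gamma).
#' @param low,high Bounds of the 95% interval.
#' @return `fit_beta()`: list with `shape1`, `shape2`, `fixed`.
#'   `fit_gamma()`: list with `shape`, `scale`, `fixed`.
#'   `fit_dirichlet()`: numeric vector of concentration parameters.
#' @export
fit_beta <- function(mean, low, high) {
  stopifnot(mean > 0, mean < 1)
  s <- (high - low) / (2 * 1.96)
  if (s == 0) return(list(shape1 = NA_real_, shape2 = NA_real_, fixed = TRUE))
  v <- s^2
  if (v >= mean * (1 - mean)) {
    abort(sprintf(
      "implied variance %.3g exceeds the beta bound %.3g for mean %.3g",
      v, mean * (1 - mean), mean
    ))
  }
  a <- mean * (mean * (1 - mean) / v - 1)
  list(shape1 = a, shape2 = a * (1 - mean) / mean, fixed = FALSE)
}

#' @rdname fit_beta
#' @export
fit_gamma <- function(mean, low, high) {
  stopifnot(mean > 0)
  s <- (high - low) / (2 * 1.96)
  if (s == 0) return(list(shape = NA_real_, scale = NA_real_, fixed = TRUE))
  list(shape = (mean / s)^2, scale = s^2 / mean, fixed = FALSE)
}

#' @rdname fit_beta
#' @param row Length-4 probability vector summing to 1.
#' @param concentration Total Dirichlet concentration (effective sample
#'   size); the fitted parameters are `row * concentration`.
#' @export
fit_dirichlet <- function(row, concentration = 1000) {
  stopifnot(length(row) == 4, abs(sum(row) - 1) < 1e-9, concentration > 0)
  row * concentration
}

# One draw from Dirichlet(alpha) via normalized gammas; zero-concentration
# components stay exactly zero (structural zeros of the transition matrix).
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, rgamma(length(alpha), shape = alpha, scale = 1), 0)
  g / sum(g)
}

# Hard feasibility check for a perturbed/sampled parameter set: probability
# bounds, matrix row sums and cost signs. Soft invariants (e.g. the utility
# ordering across NYHA classes) are deliberately not enforced here — the
# published ranges overlap across adjacent classes, and a one-way bound is a
# legitimate input even when it crosses a neighbouring mean.
perturbation_valid <- function(params) {
  probs <- c(
    params$probabilities$cv_death, params$probabilities$hf_hospitalization,
    params$probabilities$hf_readmission, params$noncv_mortality$prob,
    params$utilities$per_cycle
  )
  all(probs >= 0 & probs <= 1) &&
    all(params$costs >= 0) &&
    params$utilities$event_disutility <= 0 &&
    all(params$nyha_matrix >= 0 & params$nyha_matrix <= 1) &&
    all(abs(rowSums(params$nyha_matrix) - 1) <= 1e-9) &&
    params$settings$annual_discount >= 0
}

# Sample one value for a scalar spec row. Negative-mean beta parameters
# (the event disutility) are fitted on their magnitude and negated back.
sample_spec <- function(mean, low, high, distribution) {
  if (distribution == "beta") {
    if (mean < 0) {
      f <- fit_beta(-mean, -high, -low)
      if (f$fixed) return(mean)
      return(-rbeta(1, f$shape1, f$shape2))
    }
    f <- fit_beta(mean, low, high)
    if (f$fixed) return(mean)
    rbeta(1, f$shape1, f$shape2)
  } else if (distribution == "gamma") {
    f <- fit_gamma(mean, low, high)
    if (f$fixed) return(mean)
    rgamma(1, shape = f$shape, scale = f$scale)
  } else {
    mean
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Each uncertain parameter with a stated range is set to its low and high
#' bound in turn, all other inputs held at base case, and the comparison
#' recomputed. Entries are sorted by descending ICER spread. Perturbations
#' that violate a model invariant (e.g. a probability above 1) are flagged
#' invalid rather than clamped.
#'
#' @param params An `hf_params` object.
#' @param pair Strategy pair (see [cea_compare()]).
#' @param specs Range table; defaults to `params$specs`. Matrix-row entries
#'   (no scalar bounds) are skipped.
#' @return A tibble of class `hf_owsa` with one row per parameter: `path`,
#'   `low`, `high`, `icer_low`, `icer_high`, `verdict_low`, `verdict_high`,
#'   `nmb_low`, `nmb_high`, `spread`, `invalid`. Attributes carry the
#'   base-case ICER and the pair.
#' @export
owsa <- function(params, pair, specs = NULL) {
  specs <- specs %||% params$specs
  specs <- specs[is.finite(specs$low) & is.finite(specs$high), ]
  base <- cea_compare(params, pair)

  one_side <- function(path, value) {
    perturbed <- param_set(params, path, value)
    if (!perturbation_valid(perturbed)) {
      return(list(icer = NA_real_, verdict = "invalid", nmb = NA_real_))
    }
    res <- cea_compare(perturbed, pair)
    list(icer = res$icer, verdict = res$verdict, nmb = res$nmb)
  }

  out <- purrr::pmap_dfr(
    specs[, c("path", "low", "high")],
    function(path, low, high) {
      lo <- one_side(path, low)
      hi <- one_side(path, high)
      tibble(
        path = path, low = low, high = high,
        icer_low = lo$icer, icer_high = hi$icer,
        verdict_low = lo$verdict, verdict_high = hi$verdict,
        nmb_low = lo$nmb, nmb_high = hi$nmb,
        spread = abs(hi$icer - lo$icer),
        invalid = lo$verdict == "invalid" | hi$verdict == "invalid"
      )
    }
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$spread))
  structure(out,
    class = c("hf_owsa", class(out)),
    base_icer = base$icer, base_nmb = base$nmb, pair = base$pair
  )
}

#' Scenario presets
#'
#' Named override sets mirroring the deterministic scenario analyses:
#' hospitalization cost at five hospital levels (town to ministerial) and
#' time horizons of 5/10/15/20 years. Diabetes-subgroup scenarios require
#' subgroup transition probabilities the defaults do not contain; build them
#' with [diabetes_scenario()].
#'
#' @return Named list of override lists (parameter path -> value).
#' @export
scenario_presets <- function() {
  list(
    hospital_town = list("cost.hospitalization" = 964.07),
    hospital_county = list("cost.hospitalization" = 1120.75),
    hospital_municipal = list("cost.hospitalization" = 1785.36),
    hospital_provincial = list("cost.hospitalization" = 2812.51),
    hospital_ministerial = list("cost.hospitalization" = 3209.47),
    horizon_5 = list("horizon" = 5),
    horizon_10 = list("horizon" = 10),
    horizon_15 = list("horizon" = 15),
    horizon_20 = list("horizon" = 20)
  )
}

#' Template for a diabetes-subgroup scenario
#'
#' The subgroup analyses replace the arm-level CV-death and hospitalization
#' probabilities with user-supplied subgroup values (per 3-month cycle);
#' no defaults are bundled because the base inputs are trial-wide.
#'
#' @param cv_death Named vector of per-cycle CV-death probabilities for the
#'   arms being overridden.
#' @param hf_hospitalization Named vector of per-cycle hospitalization
#'   probabilities.
#' @return Override list for [run_scenario()].
#' @export
diabetes_scenario <- function(cv_death = NULL, hf_hospitalization = NULL) {
  ov <- list()
  for (a in names(cv_death)) ov[[paste0("cv_death.", a)]] <- cv_death[[a]]
  for (a in names(hf_hospitalization)) {
    ov[[paste0("hf_hospitalization.", a)]] <- hf_hospitalization[[a]]
  }
  if (length(ov) == 0) abort("diabetes scenario requires subgroup probabilities")
  ov
}

#' Run a deterministic scenario
#'
#' Applies a set of parameter overrides, validates the merged set, and
#' recomputes the comparison. The base parameters are untouched.
#'
#' @param params An `hf_params` object.
#' @param overrides Named list mapping parameter paths (see [param_get()]) to
#'   values, or a preset name from [scenario_presets()].
#' @param pair Strategy pair.
#' @param label Scenario label for the output; defaults to the preset name or
#'   `"custom"`.
#' @return One-row tibble: the [glance()] of the rerun comparison with a
#'   `scenario` column prepended.
#' @export
run_scenario <- function(params, overrides, pair, label = NULL) {
  if (is.character(overrides) && length(overrides) == 1) {
    presets <- scenario_presets()
    if (!overrides %in% names(presets)) {
      abort(paste0(
        "unknown scenario '", overrides, "'; available: ",
        paste(names(presets), collapse = ", ")
      ))
    }
    label <- label %||% overrides
    overrides <- presets[[overrides]]
  }
  for (path in names(overrides)) {
    params <- param_set(params, path, overrides[[path]])
  }
  validate_params(params)
  res <- cea_compare(params, pair)
  dplyr::bind_cols(tibble(scenario = label %||% "custom"), glance(res))
}

# Draw n sampled parameter sets. Returns a tibble with one column per
# sampled scalar path plus list-column nyha draws. Sampling order is the
# spec-table order, so results are reproducible for a given seed.
psa_sample <- function(params, n) {
  specs <- params$specs
  scalar <- specs[specs$distribution %in% c("beta", "gamma"), ]
  draws <- purrr::map(seq_len(n), function(i) {
    vals <- purrr::pmap_dbl(
      scalar[, c("mean", "low", "high", "distribution")], sample_spec
    )
    names(vals) <- scalar$path
    nyha <- NULL
    if (isTRUE(params$settings$sample_nyha)) {
      conc <- params$settings$dirichlet_concentration
      nyha <- t(vapply(
        NYHA_STATES,
        function(st) rdirichlet1(fit_dirichlet(params$nyha_matrix[st, ], conc)),
        numeric(4)
      ))
      dimnames(nyha) <- dimnames(params$nyha_matrix)
    }
    list(vals = vals, nyha = nyha)
  })
  draws
}

apply_draw <- function(params, draw) {
  for (path in names(draw$vals)) {
    params <- param_set(params, path, draw$vals[[path]])
  }
  if (!is.null(draw$nyha)) params$nyha_matrix <- draw$nyha
  params
}

#' Probabilistic sensitivity analysis
#'
#' Samples every uncertain parameter from its fitted distribution (Beta for
#' probabilities and utilities, Gamma for costs, Dirichlet for NYHA
#' transition rows when `settings$sample_nyha` is on; one shared draw per
#' parameter across both arms), reruns the comparison per draw, and records
#' the incremental cost/QALY pairs. Fully reproducible for a given seed.
#'
#' @param params An `hf_params` object.
#' @param pair Strategy pair.
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed.
#' @return An object of class `hf_psa`: list with `draws` (tibble: `draw`,
#'   sampled parameter columns, `dcost`, `dqaly`, `nmb`), `pair`, `wtp`,
#'   `seed`, `n_draws`.
#' @export
run_psa <- function(params, pair, n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  if (is.character(pair) && length(pair) == 1) {
    pair <- strategy_pairs()[[pair]] %||%
      abort(paste0("unknown pair '", pair, "'"))
  }
  set.seed(seed)
  samples <- psa_sample(params, n_draws)
  wtp <- params$settings$wtp_per_qaly
  rows <- purrr::imap_dfr(samples, function(draw, i) {
    p <- apply_draw(params, draw)
    res <- cea_compare(p, pair)
    dplyr::bind_cols(
      tibble(draw = i),
      as_tibble(as.list(draw$vals)),
      tibble(
        dcost = res$incremental_cost, dqaly = res$incremental_qaly,
        nmb = wtp * res$incremental_qaly - res$incremental_cost
      )
    )
  })
  structure(
    list(draws = rows, pair = pair, wtp = wtp, seed = seed, n_draws = n_draws),
    class = "hf_psa"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA draws with positive
#' net monetary benefit (`wtp * dQALY - dCost > 0`), evaluated pointwise with
#' no smoothing.
#'
#' @param psa An `hf_psa` object.
#' @param wtp_grid Non-negative WTP grid (default 0 to 30,000 by 250).
#' @return Tibble with `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 30000, by = 250)) {
  stopifnot(inherits(psa, "hf_psa"), length(wtp_grid) >= 1, all(wtp_grid >= 0))
  purrr::map_dfr(wtp_grid, function(l) {
    tibble(
      wtp = l,
      probability = mean(l * psa$draws$dqaly - psa$draws$dcost > 0)
    )
  })
}

#' Probability of cost-effectiveness at a WTP threshold
#'
#' @param psa An `hf_psa` object.
#' @param wtp Threshold in USD/QALY; defaults to the PSA's configured WTP.
#' @return Fraction of draws with positive net monetary benefit.
#' @export
probability_ce <- function(psa, wtp = NULL) {
  wtp <- wtp %||% psa$wtp
  mean(wtp * psa$draws$dqaly - psa$draws$dcost > 0)
}

#' @export
print.hf_psa <- function(x, ...) {
  cat(
    "<hf_psa>", x$pair[1], "vs", x$pair[2], "-", x$n_draws,
    "draws (seed", paste0(x$seed, ")\n")
  )
  cat(sprintf(
    "  mean dC $%.2f, mean dE %.4f QALY, P(CE at $%.2f) = %.3f\n",
    mean(x$draws$dcost), mean(x$draws$dqaly), x$wtp, probability_ce(x)
  ))
  invisible(x)
}

#' @method tidy hf_psa
#' @export
tidy.hf_psa <- function(x, ...) x$draws

#' @method glance hf_psa
#' @export
glance.hf_psa <- function(x, ...) {
  tibble(
    intervention = x$pair[1], control = x$pair[2],
    n_draws = x$n_draws, seed = x$seed, wtp = x$wtp,
    mean_dcost = mean(x$draws$dcost), mean_dqaly = mean(x$draws$dqaly),
    probability_ce = probability_ce(x)
  )
}
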