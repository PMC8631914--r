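# Patient-level microsimulation: the brute-force oracle for the cohort
# engine and a generator of synthetic trial-like cohorts.

#' Simulate individual patient trajectories
#'
#' Each patient starts in a NYHA class drawn from the initial distribution
#' and moves through the same per-cycle transition matrices the cohort engine
#' builds. Hospitalization is drawn each cycle among patients alive at its
#' start, and readmission among the hospitalized, mirroring the cohort
#' engine's expected-event arithmetic (at most one admission plus one
#' readmission per patient per cycle). Fully reproducible for a given seed.
#'
#' @param params An `hf_params` object.
#' @param strategy Arm name.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @param horizon Optional horizon override in years.
#' @return An object of class `hf_microsim`: list with `states` (n x
#'   (cycles+1) integer matrix of state codes, column k+1 = end of cycle k),
#'   `hospitalized` and `readmitted` (n x cycles logical matrices),
#'   `occupancy` (tibble of per-cycle empirical state fractions with binomial
#'   standard errors), `events` (tibble of per-cycle event counts), `n`,
#'   `seed`, `strategy`, `settings`.
#' @export
simulate_cohort <- function(params, strategy, n, seed = 1, horizon = NULL) {
  stopifnot(n >= 1)
  sp <- strategy_params(params, strategy)
  s <- params$settings
  if (!is.null(horizon)) s$horizon <- horizon
  ncyc <- round(s$horizon / s$cycle_length)
  set.seed(seed)

  states <- matrix(0L, n, ncyc + 1)
  states[, 1] <- sample.int(4, n, replace = TRUE, prob = s$initial_distribution)
  hosp <- matrix(FALSE, n, max(ncyc, 1))
  readm <- matrix(FALSE, n, max(ncyc, 1))

  for (k in seq_len(ncyc)) {
    age <- s$start_age + (k - 1) * s$cycle_length
    m <- build_cycle_matrix(sp, params$nyha_matrix, params, age)
    cur <- states[, k]
    nxt <- cur
    for (st in 1:4) {
      idx <- which(cur == st)
      if (length(idx) > 0) {
        nxt[idx] <- sample.int(6, length(idx), replace = TRUE, prob = m[st, ])
      }
    }
    alive_start <- cur <= 4L
    h <- alive_start & runif(n) < sp$hosp_per_cycle
    r <- h & runif(n) < sp$readmit_per_hosp
    states[, k + 1] <- nxt
    hosp[, k] <- h
    readm[, k] <- r
  }

  occ <- purrr::map_dfr(seq_len(ncyc + 1) - 1, function(k) {
    cnt <- tabulate(states[, k + 1], nbins = 6)
    p <- cnt / n
    tibble(
      cycle = k, state = HF_STATES, fraction = p,
      se = sqrt(p * (1 - p) / n)
    )
  })
  events <- if (ncyc == 0) {
    tibble(
      cycle = integer(), hospitalizations = integer(), readmissions = integer()
    )
  } else {
    tibble(
      cycle = seq_len(ncyc),
      hospitalizations = colSums(hosp)[seq_len(ncyc)],
      readmissions = colSums(readm)[seq_len(ncyc)]
    )
  }
  structure(
    list(
      states = states, hospitalized = hosp, readmitted = readm,
      occupancy = occ, events = events,
      n = n, seed = seed, strategy = strategy, settings = s
    ),
    class = "hf_microsim"
  )
}

#' Per-patient cost/QALY accumulation over a simulated cohort
#'
#' Applies the same accounting conventions as [cea_accumulate()] — half-cycle
#' corrected state terms, full event terms, identical discounting — to each
#' simulated patient, and reports cohort means with Monte Carlo standard
#' errors.
#'
#' @param cohort An `hf_microsim` from [simulate_cohort()].
#' @param params The `hf_params` the cohort was simulated under.
#' @return One-row tibble with `strategy`, `mean_cost`, `se_cost`,
#'   `mean_qaly`, `se_qaly`, `n`.
#' @export
microsim_cea <- function(cohort, params) {
  stopifnot(inherits(cohort, "hf_microsim"))
  sp <- strategy_params(params, cohort$strategy)
  s <- cohort$settings
  for (f in c("annual_discount", "half_cycle_correction", "discount_convention")) {
    if (!identical(s[[f]], params$settings[[f]])) {
      abort(paste0("cohort was simulated under different settings: ", f))
    }
  }
  ncyc <- ncol(cohort$states) - 1
  n <- cohort$n
  util6 <- c(params$utilities$per_cycle, DEAD_CV = 0, DEAD_NONCV = 0)
  cost <- numeric(n)
  qaly <- numeric(n)
  if (ncyc > 0) {
    for (k in seq_len(ncyc)) {
      t_start <- (k - 1) * s$cycle_length
      t_end <- k * s$cycle_length
      td <- if (s$discount_convention == "mid_cycle") (t_start + t_end) / 2 else t_start
      d <- discount_factor(td, s$annual_discount)
      alive_s <- as.numeric(cohort$states[, k] <= 4L)
      alive_e <- as.numeric(cohort$states[, k + 1] <= 4L)
      u_s <- util6[cohort$states[, k]]
      u_e <- util6[cohort$states[, k + 1]]
      w_alive <- if (isTRUE(s$half_cycle_correction)) (alive_s + alive_e) / 2 else alive_s
      w_util <- if (isTRUE(s$half_cycle_correction)) (u_s + u_e) / 2 else u_s
      ev <- cohort$hospitalized[, k] + cohort$readmitted[, k]
      cost <- cost + d * (
        w_alive * (sp$standard_cost_per_cycle + sp$drug_cost_per_cycle) +
          ev * sp$hosp_cost_per_event
      )
      qaly <- qaly + d * (w_util + ev * params$utilities$event_disutility)
    }
  }
  tibble(
    strategy = cohort$strategy,
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
    mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
    n = n
  )
}

#' Synthesize a trial-like outcome proportion from a per-cycle probability
#'
#' Simulates `n` patients under a constant per-cycle event probability for
#' `followup_months / 3` cycles (rounded to the nearest whole cycle) and
#' returns the fraction with at least one event — the quantity a trial
#' reports. Feeding the result back through [prob_per_cycle()] recovers the
#' true per-cycle probability up to Monte Carlo error, which is how the DEALE
#' conversion is validated by parameter recovery.
#'
#' @param true_per_cycle_prob Per-cycle event probability in `[0, 1]`.
#' @param followup_months Follow-up in months (rounded to a whole number of
#'   3-month cycles).
#' @param n_per_arm Number of simulated patients.
#' @param seed Integer seed.
#' @return List of class `hf_trial` with `event_proportion`,
#'   `followup_months` (after rounding), `n`, `seed`.
#' @export
synthesize_trial <- function(true_per_cycle_prob, followup_months, n_per_arm,
                             seed = 1) {
  stopifnot(
    true_per_cycle_prob >= 0, true_per_cycle_prob <= 1,
    followup_months > 0, n_per_arm >= 1
  )
  ncyc <- max(1L, round(followup_months / 3))
  set.seed(seed)
  n_events <- rbinom(n_per_arm, size = ncyc, prob = true_per_cycle_prob)
  structure(
    list(
      event_proportion = mean(n_events > 0),
      followup_months = ncyc * 3,
      n = n_per_arm, seed = seed
    ),
    class = "hf_trial"
  )
}

#' Export simulated histories in long format
#'
#' @param cohort An `hf_microsim`.
#' @param patients Optional subset of patient indices.
#' @return Tibble with `patient`, `cycle`, `state`, `hospitalized`,
#'   `readmitted` (events refer to the cycle ending at `cycle`; cycle 0 rows
#'   carry the initial state and no events).
#' @export
microsim_histories <- function(cohort, patients = NULL) {
  stopifnot(inherits(cohort, "hf_microsim"))
  patients <- patients %||% seq_len(cohort$n)
  ncyc <- ncol(cohort$states) - 1
  purrr::map_dfr(patients, function(p) {
    tibble(
      patient = p,
      cycle = 0:ncyc,
      state = HF_STATES[cohort$states[p, ]],
      hospitalized = c(FALSE, if (ncyc > 0) cohort$hospitalized[p, seq_len(ncyc)]),
      readmitted = c(FALSE, if (ncyc > 0) cohort$readmitted[p, seq_len(ncyc)])
    )
  })
}
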