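# Cohort engine: per-cycle transition matrices over the six states and the
# deterministic trace of state occupancy and expected event counts.

# Per-cycle non-CV death probability at an attained age. Band lookup uses the
# floored age; ages beyond the last band carry its value forward (documented
# extrapolation for horizons reaching past the table).
noncv_prob_at <- function(params, age) {
  bands <- params$noncv_mortality
  a <- floor(age + 1e-9)
  if (a < bands$age_low[1]) {
    abort(sprintf("age %g below the first non-CV mortality band", age))
  }
  i <- findInterval(a, bands$age_low)
  p <- bands$prob[i]
  if (isTRUE(params$settings$noncv_mortality_is_annual)) {
    p <- annual_prob_to_cycle(p, params$settings$cycle_length)
  }
  p
}

#' Assemble the one-cycle transition matrix for a strategy at a given age
#'
#' For each living NYHA state the cycle applies the arm's cardiovascular death
#' probability and the age-band non-cardiovascular death probability
#' additively; survivors are redistributed across NYHA classes by the
#' transition matrix. Death rows are absorbing.
#'
#' @param strategy One-row tibble from [strategy_params()] (or a list with a
#'   `cv_death_per_cycle` field).
#' @param nyha 4x4 NYHA-to-NYHA per-cycle transition matrix.
#' @param params An `hf_params` object (supplies the non-CV mortality table
#'   and conventions).
#' @param age Attained age in years at the start of the cycle.
#' @return 6x6 row-stochastic matrix over
#'   `NYHA1..NYHA4, DEAD_CV, DEAD_NONCV`.
#' @export
build_cycle_matrix <- function(strategy, nyha, params, age) {
  p_cv <- strategy$cv_death_per_cycle
  p_nc <- noncv_prob_at(params, age)
  if (p_cv + p_nc > 1) {
    abort(sprintf(
      "death probabilities exceed 1 at age %g (cv %.4f + non-cv %.4f)",
      age, p_cv, p_nc
    ))
  }
  m <- matrix(0, 6, 6, dimnames = list(HF_STATES, HF_STATES))
  m[1:4, 1:4] <- (1 - p_cv - p_nc) * nyha
  m[1:4, "DEAD_CV"] <- p_cv
  m[1:4, "DEAD_NONCV"] <- p_nc
  m["DEAD_CV", "DEAD_CV"] <- 1
  m["DEAD_NONCV", "DEAD_NONCV"] <- 1
  m
}

#' Run the deterministic cohort model for one strategy
#'
#' Iterates the cohort from the initial NYHA distribution through
#' `horizon / cycle_length` cycles, advancing age each cycle and recording
#' start/end occupancy plus expected event counts. Hospitalization is an
#' event overlaid on the state process: the at-risk population in a cycle is
#' the fraction alive at its start, and each hospitalization carries a fixed
#' readmission probability within the same cycle.
#'
#' @param params An `hf_params` object.
#' @param strategy Arm name (see [strategy_names()]).
#' @param horizon Time horizon in years; defaults to `params$settings$horizon`.
#' @return A tibble of class `hf_trace`, one row per cycle, with columns
#'   `cycle`, `age`, `time_start`, `time_end`, `start_*`/`end_*` occupancy for
#'   the six states, `alive_start`, `alive_end`, `hospitalizations`,
#'   `readmissions`, `cv_deaths`, `noncv_deaths` (expected events per initial
#'   patient). Attributes `strategy` and `settings` record provenance.
#' @export
run_cohort <- function(params, strategy, horizon = NULL) {
  sp <- strategy_params(params, strategy)
  s <- params$settings
  if (!is.null(horizon)) s$horizon <- horizon
  ncyc <- s$horizon / s$cycle_length
  if (ncyc < 0 || abs(ncyc - round(ncyc)) > 1e-9) {
    abort("horizon must be a non-negative integer multiple of cycle_length")
  }
  ncyc <- round(ncyc)

  occ <- c(s$initial_distribution, 0, 0)
  names(occ) <- HF_STATES
  if (ncyc == 0) {
    row <- c(
      cycle = 0, age = s$start_age, time_start = 0, time_end = 0,
      setNames(occ, paste0("start_", HF_STATES)),
      setNames(occ, paste0("end_", HF_STATES)),
      alive_start = sum(occ[1:4]), alive_end = sum(occ[1:4]),
      hospitalizations = 0, readmissions = 0, cv_deaths = 0, noncv_deaths = 0
    )
    return(new_trace(dplyr::bind_rows(row), strategy, s))
  }

  rows <- vector("list", ncyc)
  for (k in seq_len(ncyc)) {
    age <- s$start_age + (k - 1) * s$cycle_length
    m <- build_cycle_matrix(sp, params$nyha_matrix, params, age)
    occ_end <- drop(occ %*% m)
    alive_start <- sum(occ[1:4])
    hosp <- alive_start * sp$hosp_per_cycle
    readm <- hosp * sp$readmit_per_hosp
    rows[[k]] <- c(
      cycle = k, age = age,
      time_start = (k - 1) * s$cycle_length, time_end = k * s$cycle_length,
      setNames(occ, paste0("start_", HF_STATES)),
      setNames(occ_end, paste0("end_", HF_STATES)),
      alive_start = alive_start, alive_end = sum(occ_end[1:4]),
      hospitalizations = hosp, readmissions = readm,
      cv_deaths = occ_end[["DEAD_CV"]] - occ[["DEAD_CV"]],
      noncv_deaths = occ_end[["DEAD_NONCV"]] - occ[["DEAD_NONCV"]]
    )
    occ <- occ_end
  }
  new_trace(as_tibble(do.call(rbind, rows)), strategy, s)
}

new_trace <- function(df, strategy, settings) {
  structure(df,
    class = c("hf_trace", class(df)),
    strategy = strategy, settings = settings
  )
}

#' Survival curve from a cohort trace
#'
#' @param trace An `hf_trace` from [run_cohort()].
#' @return Tibble with columns `time` (years, cycle boundaries including 0)
#'   and `alive` (fraction of the initial cohort alive); non-increasing.
#' @export
survival_curve <- function(trace) {
  stopifnot(inherits(trace, "hf_trace"))
  tibble(
    time = c(trace$time_start[1], trace$time_end),
    alive = c(trace$alive_start[1], trace$alive_end)
  )
}

#' Median survival on the cycle grid
#'
#' Locates the pair of consecutive cycle boundaries between which the alive
#' fraction crosses 0.5. The point estimate is the lower endpoint of that
#' bracket by default — the last boundary at which more than half the cohort
#' is alive, i.e. the grid time within whose following cycle the median is
#' reached. `convention = "first_at_or_below"` instead reports the first
#' boundary at which the alive fraction is at or below 0.5 (the bracket's
#' upper endpoint).
#'
#' @param trace An `hf_trace`.
#' @param convention `"bracket_lower"` (default) or `"first_at_or_below"`.
#' @return One-row tibble with `median` (years; `NA` if censored),
#'   `bracket_lower`, `bracket_upper` and `censored` (TRUE when the alive
#'   fraction stays above 0.5 through the horizon, i.e. median > horizon).
#' @export
median_survival <- function(trace, convention = c("bracket_lower", "first_at_or_below")) {
  convention <- match.arg(convention)
  sc <- survival_curve(trace)
  below <- which(sc$alive <= 0.5)
  if (length(below) == 0) {
    return(tibble(
      median = NA_real_, bracket_lower = max(sc$time),
      bracket_upper = NA_real_, censored = TRUE
    ))
  }
  i <- below[1]
  lower <- if (i == 1) sc$time[1] else sc$time[i - 1]
  upper <- sc$time[i]
  tibble(
    median = if (convention == "bracket_lower") lower else upper,
    bracket_lower = lower, bracket_upper = upper, censored = FALSE
  )
}

#' Cumulative event rates at a time point
#'
#' Cumulative death occupancy and expected hospitalization episodes
#' (admissions plus readmissions) per initial patient at a cycle boundary,
#' expressed as percentages. Used to compare the model against trial-reported
#' mortality and hospitalization proportions.
#'
#' @param trace An `hf_trace`.
#' @param at_months Time point in months; must be a multiple of the cycle
#'   length and within the horizon.
#' @return One-row tibble with `all_cause_mortality`, `cv_mortality` and
#'   `hf_hospitalization`, all in percent.
#' @export
cumulative_event_rates <- function(trace, at_months) {
  stopifnot(inherits(trace, "hf_trace"))
  s <- attr(trace, "settings")
  cyc_months <- s$cycle_length * 12
  k <- at_months / cyc_months
  if (abs(k - round(k)) > 1e-9) {
    abort("at_months must be a multiple of the cycle length")
  }
  k <- round(k)
  if (k > max(trace$cycle)) abort("at_months lies beyond the horizon")
  if (k == 0) {
    return(tibble(
      all_cause_mortality = 0, cv_mortality = 0, hf_hospitalization = 0
    ))
  }
  row <- trace[trace$cycle == k, ]
  upto <- trace$cycle >= 1 & trace$cycle <= k
  tibble(
    all_cause_mortality = 100 * (row$end_DEAD_CV + row$end_DEAD_NONCV),
    cv_mortality = 100 * row$end_DEAD_CV,
    hf_hospitalization = 100 * sum(
      trace$hospitalizations[upto] + trace$readmissions[upto]
    )
  )
}

#' Export a cohort trace as a tidy CSV
#'
#' @param trace An `hf_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$strategy <- attr(trace, "strategy")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
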