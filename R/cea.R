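# Discounted cost/QALY accumulation over a cohort trace and incremental
# cost-effectiveness statistics.

# Per-cycle discount factors and state-occupancy weights under the configured
# conventions. State (person-time) terms optionally use the trapezoid of
# start/end occupancy (half-cycle correction); event terms are counted in
# full in the cycle they occur. Mid-cycle discounting evaluates the factor at
# the middle of each cycle, start_of_cycle at its beginning.
cycle_weights <- function(trace, settings) {
  td <- if (settings$discount_convention == "mid_cycle") {
    (trace$time_start + trace$time_end) / 2
  } else {
    trace$time_start
  }
  discount_factor(td, settings$annual_discount)
}

state_occupancy <- function(trace, settings, states) {
  s_cols <- as.matrix(trace[paste0("start_", states)])
  e_cols <- as.matrix(trace[paste0("end_", states)])
  if (isTRUE(settings$half_cycle_correction)) (s_cols + e_cols) / 2 else s_cols
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per cycle, the alive occupancy accrues standard-treatment plus drug costs
#' and state utilities (half-cycle corrected when enabled); each expected
#' hospitalization or readmission event adds its cost and a one-time utility
#' decrement. All terms are discounted at the configured convention and
#' summed over cycles.
#'
#' @param trace An `hf_trace` from [run_cohort()].
#' @param params The `hf_params` the trace was produced under.
#' @param strategy Arm name; defaults to the trace's own strategy.
#' @return One-row tibble with `strategy`, `total_cost` (USD) and
#'   `total_qaly`, plus component columns `state_cost`, `event_cost`,
#'   `state_qaly`, `event_qaly`.
#' @export
cea_accumulate <- function(trace, params, strategy = NULL) {
  stopifnot(inherits(trace, "hf_trace"))
  strategy <- strategy %||% attr(trace, "strategy")
  sp <- strategy_params(params, strategy)
  settings <- attr(trace, "settings")
  for (f in c("annual_discount", "half_cycle_correction", "discount_convention")) {
    if (!identical(settings[[f]], params$settings[[f]])) {
      abort(paste0("trace was produced under different settings: ", f))
    }
  }
  live <- trace$cycle >= 1
  tr <- trace[live, ]
  if (nrow(tr) == 0) {
    return(tibble(
      strategy = strategy, total_cost = 0, total_qaly = 0,
      state_cost = 0, event_cost = 0, state_qaly = 0, event_qaly = 0
    ))
  }
  d <- cycle_weights(tr, settings)
  occ <- state_occupancy(tr, settings, NYHA_STATES)
  alive <- rowSums(occ)
  events <- tr$hospitalizations + tr$readmissions

  state_cost <- sum(d * alive * (sp$standard_cost_per_cycle + sp$drug_cost_per_cycle))
  event_cost <- sum(d * events * sp$hosp_cost_per_event)
  state_qaly <- sum(d * (occ %*% params$utilities$per_cycle))
  event_qaly <- sum(d * events * params$utilities$event_disutility)
  tibble(
    strategy = strategy,
    total_cost = state_cost + event_cost,
    total_qaly = state_qaly + event_qaly,
    state_cost = state_cost, event_cost = event_cost,
    state_qaly = state_qaly, event_qaly = event_qaly
  )
}

icer_verdict <- function(dc, de, eps = 1e-12) {
  if (abs(dc) < eps && abs(de) < eps) {
    list(icer = NA_real_, tag = "no_difference")
  } else if (de > eps && dc <= eps) {
    list(icer = NA_real_, tag = "dominant")
  } else if (de < -eps && dc >= -eps) {
    list(icer = NA_real_, tag = "dominated")
  } else if (de > eps && dc > eps) {
    list(icer = dc / de, tag = "icer")
  } else {
    # both negative (or effect ~0): no meaningful positive ICER to report
    list(icer = NA_real_, tag = "trade_off")
  }
}

ce_category <- function(icer, tag, gdp) {
  if (tag == "dominant") return("dominant")
  if (tag == "dominated") return("dominated")
  if (!is.finite(icer)) return(NA_character_)
  if (icer < gdp) "very_cost_effective"
  else if (icer <= 3 * gdp) "cost_effective"
  else "not_cost_effective"
}

#' Compare an intervention against its control
#'
#' Runs both arms of a strategy pair, accumulates discounted costs and QALYs,
#' and derives the incremental statistics: incremental cost and QALYs, the
#' ICER (or a dominance verdict), net monetary benefit at the willingness-to-
#' pay threshold, and the WHO GDP-multiple cost-effectiveness category
#' (`very_cost_effective` below 1x GDP per capita, `cost_effective` up to 3x,
#' `not_cost_effective` above).
#'
#' @param params An `hf_params` object.
#' @param pair Length-2 character vector `c(intervention, control)` or a name
#'   from [strategy_pairs()] (`"dapa"` or `"empa"`).
#' @param horizon Optional horizon override in years.
#' @return An object of class `hf_cea`: list with `arms` (two-row tibble of
#'   totals), `incremental_cost`, `incremental_qaly`, `icer`, `verdict`,
#'   `nmb`, `category`, `wtp`, `gdp`, `pair`.
#' @export
#' @examples
#' res <- cea_compare(default_params(), "dapa")
#' glance(res)
cea_compare <- function(params, pair, horizon = NULL) {
  if (is.character(pair) && length(pair) == 1) {
    pairs <- strategy_pairs()
    if (!pair %in% names(pairs)) {
      abort(paste0(
        "unknown pair '", pair, "'; use one of: ",
        paste(names(pairs), collapse = ", "), " or c(intervention, control)"
      ))
    }
    pair <- pairs[[pair]]
  }
  stopifnot(length(pair) == 2)
  res <- purrr::map(pair, function(arm) {
    cea_accumulate(run_cohort(params, arm, horizon = horizon), params, arm)
  })
  arms <- dplyr::bind_rows(res) |>
    dplyr::mutate(role = c("intervention", "control"), .after = "strategy")
  dc <- arms$total_cost[1] - arms$total_cost[2]
  de <- arms$total_qaly[1] - arms$total_qaly[2]
  v <- icer_verdict(dc, de)
  wtp <- params$settings$wtp_per_qaly
  gdp <- params$settings$gdp_per_capita
  structure(
    list(
      arms = arms,
      incremental_cost = dc, incremental_qaly = de,
      icer = v$icer, verdict = v$tag,
      nmb = wtp * de - dc,
      category = ce_category(v$icer, v$tag, gdp),
      wtp = wtp, gdp = gdp, pair = pair
    ),
    class = "hf_cea"
  )
}

#' @export
print.hf_cea <- function(x, ...) {
  cat("<hf_cea>", x$pair[1], "vs", x$pair[2], "\n")
  print(dplyr::select(x$arms, "strategy", "role", "total_cost", "total_qaly"))
  cat(sprintf(
    "  incremental: $%.2f / %.4f QALY\n", x$incremental_cost, x$incremental_qaly
  ))
  if (x$verdict == "icer") {
    cat(sprintf("  ICER: $%.2f per QALY (%s)\n", x$icer, x$category))
  } else {
    cat("  verdict:", x$verdict, "\n")
  }
  cat(sprintf("  NMB at WTP $%.2f: $%.2f\n", x$wtp, x$nmb))
  invisible(x)
}

#' Tidy the per-arm totals of a comparison
#'
#' @param x An `hf_cea` object.
#' @param ... Unused.
#' @return The two-row arms tibble (strategy, role, discounted totals and
#'   their cost/QALY components).
#' @method tidy hf_cea
#' @export
tidy.hf_cea <- function(x, ...) x$arms

#' One-row summary of a comparison
#'
#' @param x An `hf_cea` object.
#' @param ... Unused.
#' @return One-row tibble with the incremental statistics, ICER/verdict, NMB
#'   and cost-effectiveness category.
#' @method glance hf_cea
#' @export
glance.hf_cea <- function(x, ...) {
  tibble(
    intervention = x$pair[1], control = x$pair[2],
    intervention_cost = x$arms$total_cost[1],
    intervention_qaly = x$arms$total_qaly[1],
    control_cost = x$arms$total_cost[2],
    control_qaly = x$arms$total_qaly[2],
    incremental_cost = x$incremental_cost,
    incremental_qaly = x$incremental_qaly,
    icer = x$icer, verdict = x$verdict, nmb = x$nmb, category = x$category
  )
}
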