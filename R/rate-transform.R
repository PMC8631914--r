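#' DEALE conversion of a trial event proportion to a per-cycle probability
#'
#' Trials report the fraction of patients with at least one event over a
#' follow-up period. Under the declining-exponential (constant hazard)
#' approximation the survival fraction `S = 1 - event_proportion` observed
#' over `t` cycles implies a per-cycle rate `r = -log(S) / t`, which converts
#' to a per-cycle transition probability `P = 1 - exp(-r)`.
#'
#' @param event_proportion Fraction of the cohort with >= 1 event over
#'   follow-up, in `[0, 1)`.
#' @param followup_months Follow-up duration in months (> 0).
#' @param cycle_length_months Model cycle length in months (default 3).
#' @return Per-cycle transition probability in `[0, 1)`.
#' @export
#' @examples
#' prob_per_cycle(0.096, 18.2) # trial CV-mortality proportion -> 0.01650
prob_per_cycle <- function(event_proportion, followup_months,
                           cycle_length_months = 3) {
  if (any(event_proportion < 0 | event_proportion >= 1)) {
    abort("event_proportion must lie in [0, 1): the implied hazard is infinite at 1")
  }
  if (any(followup_months <= 0) || cycle_length_months <= 0) {
    abort("followup_months and cycle_length_months must be positive")
  }
  t_cycles <- followup_months / cycle_length_months
  r <- -log(1 - event_proportion) / t_cycles
  1 - exp(-r)
}

#' Convert an annual probability to a shorter-cycle probability
#'
#' Constant-hazard rescaling `1 - (1 - p)^cycle_length`, used when a
#' probability quoted per year (e.g. an annual background-mortality reading)
#' must be applied per model cycle.
#'
#' @param p_annual Annual probability in `[0, 1)`.
#' @param cycle_length Cycle length in years.
#' @return Per-cycle probability in `[0, p_annual]` for `cycle_length <= 1`.
#' @export
annual_prob_to_cycle <- function(p_annual, cycle_length) {
  if (any(p_annual < 0 | p_annual >= 1)) {
    abort("p_annual must lie in [0, 1)")
  }
  1 - (1 - p_annual)^cycle_length
}

#' Discount factor at an annual rate
#'
#' @param time Time in years (>= 0).
#' @param annual_rate Annual discount rate (>= 0).
#' @return `(1 + annual_rate)^(-time)`.
#' @export
discount_factor <- function(time, annual_rate) {
  stopifnot(all(time >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-time)
}

#' Compound a cost forward at an annual rate
#'
#' @param amount Cost (>= 0).
#' @param annual_rate Annual compounding rate.
#' @param years Number of years to compound over.
#' @return `amount * (1 + annual_rate)^years`.
#' @export
#' @examples
#' inflate_cost(102.75, 0.05, 3) # 118.95
inflate_cost <- function(amount, annual_rate, years) {
  stopifnot(all(amount >= 0))
  amount * (1 + annual_rate)^years
}

#' Convert Chinese yuan to US dollars
#'
#' Fixed conversion at 6.44 CNY per USD (2020 exchange rate used for all
#' monetary inputs).
#'
#' @param amount_cny Amount in CNY.
#' @return Amount in USD.
#' @export
cny_to_usd <- function(amount_cny) amount_cny / 6.44
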