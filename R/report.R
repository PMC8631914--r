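# Report generation: CSV/JSON outputs, figures, and run manifests. These
# functions back the command-line wrapper in scripts/hfcea.R.

#' Write a run manifest
#'
#' Every report command records how it was produced: the command name, the
#' configuration source, the seed, a timestamp, the package version and the
#' list of files it wrote. Re-running the same command with the same inputs
#' reproduces the data outputs.
#'
#' @param command Command label (e.g. `"base-case"`).
#' @param config Config path or `"defaults"`.
#' @param seed Integer seed or `NA` for deterministic commands.
#' @param outputs Character vector of files written.
#' @param out_dir Output directory.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(command, config, seed, outputs, out_dir) {
  manifest <- list(
    command = command,
    config = config,
    seed = if (is.na(seed)) NULL else seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("hfcea")),
    outputs = as.list(outputs)
  )
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Base-case report
#'
#' Writes the per-arm totals, incrementals and ICER for one or both strategy
#' pairs as CSV and JSON, plus a validation block (median survival and
#' 18-month cumulative event rates per arm) and a manifest.
#'
#' @param params An `hf_params` object.
#' @param pairs Pair names (default both).
#' @param out_dir Output directory (created if needed).
#' @param config Config label recorded in the manifest.
#' @return Tibble of results, invisibly.
#' @export
report_base_case <- function(params, pairs = names(strategy_pairs()),
                             out_dir = ".", config = "defaults") {
  ensure_dir(out_dir)
  results <- purrr::map_dfr(pairs, function(p) glance(cea_compare(params, p)))
  csv <- file.path(out_dir, "base_case.csv")
  write.csv(as.data.frame(results), csv, row.names = FALSE)

  validation <- purrr::map(
    setNames(strategy_names(params), strategy_names(params)),
    function(arm) {
      trace <- run_cohort(params, arm)
      ms <- median_survival(trace)
      rates <- cumulative_event_rates(trace, 18)
      list(
        median_survival_years = ms$median,
        median_censored = ms$censored,
        at_18_months = as.list(rates)
      )
    }
  )
  js <- file.path(out_dir, "base_case.json")
  jsonlite::write_json(
    list(results = results, validation = validation),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_manifest("base-case", config, NA, c(csv, js), out_dir)
  invisible(results)
}

#' One-way sensitivity report
#'
#' @param params An `hf_params` object.
#' @param pair Pair name.
#' @param out_dir Output directory.
#' @param config Config label for the manifest.
#' @param figure Write a tornado PNG alongside the CSV.
#' @return The `hf_owsa` tibble, invisibly.
#' @export
report_owsa <- function(params, pair, out_dir = ".", config = "defaults",
                        figure = TRUE) {
  ensure_dir(out_dir)
  res <- owsa(params, pair)
  csv <- file.path(out_dir, paste0("owsa_", pair, ".csv"))
  write.csv(as.data.frame(res), csv, row.names = FALSE)
  outputs <- csv
  if (figure) {
    fig <- file.path(out_dir, paste0("tornado_", pair, ".png"))
    ggplot2::ggsave(fig, autoplot(res), width = 8, height = 6, dpi = 150)
    outputs <- c(outputs, fig)
  }
  write_manifest(paste0("owsa-", pair), config, NA, outputs, out_dir)
  invisible(res)
}

#' Scenario-analysis report
#'
#' Runs every preset scenario (hospital levels and time horizons) for the
#' given pair and writes the ICER table.
#'
#' @param params An `hf_params` object.
#' @param pair Pair name.
#' @param out_dir Output directory.
#' @param config Config label for the manifest.
#' @return Tibble of scenario results, invisibly.
#' @export
report_scenarios <- function(params, pair, out_dir = ".", config = "defaults") {
  ensure_dir(out_dir)
  res <- purrr::imap_dfr(
    scenario_presets(),
    function(ov, label) run_scenario(params, ov, pair, label = label)
  )
  csv <- file.path(out_dir, paste0("scenarios_", pair, ".csv"))
  write.csv(as.data.frame(res), csv, row.names = FALSE)
  write_manifest(paste0("scenario-", pair), config, NA, csv, out_dir)
  invisible(res)
}

#' Probabilistic sensitivity report
#'
#' Writes the per-draw incremental pairs, the CEAC table, and (optionally)
#' the acceptability-curve and cost-effectiveness-plane figures.
#'
#' @param params An `hf_params` object.
#' @param pair Pair name.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param config Config label for the manifest.
#' @param figure Write PNG figures.
#' @return The `hf_psa` object, invisibly.
#' @export
report_psa <- function(params, pair, n_draws = 1000, seed = 1, out_dir = ".",
                       config = "defaults", figure = TRUE) {
  ensure_dir(out_dir)
  psa <- run_psa(params, pair, n_draws = n_draws, seed = seed)
  draws_csv <- file.path(out_dir, paste0("psa_draws_", pair, ".csv"))
  write.csv(as.data.frame(psa$draws), draws_csv, row.names = FALSE)
  curve <- ceac(psa)
  ceac_csv <- file.path(out_dir, paste0("ceac_", pair, ".csv"))
  write.csv(as.data.frame(curve), ceac_csv, row.names = FALSE)
  outputs <- c(draws_csv, ceac_csv)
  if (figure) {
    f1 <- file.path(out_dir, paste0("ceac_", pair, ".png"))
    ggplot2::ggsave(f1, plot_ceac(curve, psa$wtp), width = 7, height = 5, dpi = 150)
    f2 <- file.path(out_dir, paste0("ce_plane_", pair, ".png"))
    ggplot2::ggsave(f2, autoplot(psa), width = 7, height = 5, dpi = 150)
    outputs <- c(outputs, f1, f2)
  }
  write_manifest(paste0("psa-", pair), config, seed, outputs, out_dir)
  invisible(psa)
}

#' Microsimulation report
#'
#' Simulates a patient-level cohort for one arm and writes the empirical
#' occupancy/event tables plus per-patient mean cost and QALY.
#'
#' @param params An `hf_params` object.
#' @param strategy Arm name.
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param config Config label for the manifest.
#' @return The `hf_microsim`, invisibly.
#' @export
report_microsim <- function(params, strategy, n = 10000, seed = 1,
                            out_dir = ".", config = "defaults") {
  ensure_dir(out_dir)
  sim <- simulate_cohort(params, strategy, n, seed = seed)
  occ_csv <- file.path(out_dir, paste0("microsim_occupancy_", strategy, ".csv"))
  write.csv(as.data.frame(sim$occupancy), occ_csv, row.names = FALSE)
  ev_csv <- file.path(out_dir, paste0("microsim_events_", strategy, ".csv"))
  write.csv(as.data.frame(sim$events), ev_csv, row.names = FALSE)
  cea_csv <- file.path(out_dir, paste0("microsim_cea_", strategy, ".csv"))
  write.csv(as.data.frame(microsim_cea(sim, params)), cea_csv, row.names = FALSE)
  write_manifest(
    paste0("simulate-", strategy), config, seed,
    c(occ_csv, ev_csv, cea_csv), out_dir
  )
  invisible(sim)
}
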