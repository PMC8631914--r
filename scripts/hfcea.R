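#!/usr/bin/env Rscript
# Thin command-line wrapper over the hfcea report functions.
#
# Usage: Rscript scripts/hfcea.R <command> [options]
# Commands: base-case, owsa, scenario, psa, validate, simulate
#
# Exit codes: 0 success, 2 usage/config error, 1 runtime error. Logging goes
# to standard error; data is written to --out.

suppressPackageStartupMessages({
  library(optparse)
  library(hfcea)
})

usage_error <- function(msg) {
  message(msg)
  quit(status = 2)
}

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) {
  usage_error("usage: hfcea.R {base-case|owsa|scenario|psa|validate|simulate} [options]")
}
command <- argv[1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON config overriding the bundled defaults"),
  make_option("--out", type = "character", default = "hfcea_out",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = 1,
              help = "seed for stochastic commands [default %default]"),
  make_option("--pair", type = "character", default = "dapa",
              help = "strategy pair: dapa or empa [default %default]"),
  make_option("--strategy", type = "character", default = "dapagliflozin",
              help = "arm for 'simulate' [default %default]"),
  make_option("--horizon", type = "double", default = NULL,
              help = "horizon override in years"),
  make_option("--n-draws", type = "integer", default = 1000, dest = "n_draws",
              help = "PSA draws [default %default]"),
  make_option("--n-patients", type = "integer", default = 10000, dest = "n_patients",
              help = "microsimulation size [default %default]"),
  make_option("--label", type = "character", default = NULL,
              help = "scenario preset label (see scenario_presets())")
))
opts <- tryCatch(
  parse_args(parser, args = argv[-1]),
  error = function(e) usage_error(conditionMessage(e))
)

if (!command %in% c("base-case", "owsa", "scenario", "psa", "validate", "simulate")) {
  usage_error(paste0("unknown command: ", command))
}
if (!opts$pair %in% names(strategy_pairs())) {
  usage_error(paste0("unknown pair: ", opts$pair, " (use dapa or empa)"))
}
if (command == "psa" && opts$n_draws < 1) usage_error("--n-draws must be >= 1")

run <- function() {
  params <- if (is.null(opts$config)) default_params() else load_config(opts$config)
  if (!is.null(opts$horizon)) {
    params <- param_set(params, "horizon", opts$horizon)
    validate_params(params)
  }
  config_label <- if (is.null(opts$config)) "defaults" else opts$config
  out <- opts$out

  if (command == "base-case") {
    res <- report_base_case(params, out_dir = out, config = config_label)
    message(sprintf(
      "base case written to %s (ICERs: %s)", out,
      paste(sprintf("%s %.2f", res$intervention, res$icer), collapse = ", ")
    ))
  } else if (command == "owsa") {
    report_owsa(params, opts$pair, out_dir = out, config = config_label)
    message("one-way sensitivity analysis written to ", out)
  } else if (command == "scenario") {
    if (!is.null(opts$label)) {
      if (!opts$label %in% names(scenario_presets())) {
        usage_error(paste0(
          "unknown scenario label: ", opts$label, "\navailable: ",
          paste(names(scenario_presets()), collapse = ", ")
        ))
      }
      res <- run_scenario(params, opts$label, opts$pair)
      csv <- file.path(out, paste0("scenario_", opts$label, "_", opts$pair, ".csv"))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write.csv(as.data.frame(res), csv, row.names = FALSE)
      write_manifest(paste0("scenario-", opts$label), config_label, NA, csv, out)
    } else {
      report_scenarios(params, opts$pair, out_dir = out, config = config_label)
    }
    message("scenario analysis written to ", out)
  } else if (command == "psa") {
    psa <- report_psa(params, opts$pair,
      n_draws = opts$n_draws, seed = opts$seed,
      out_dir = out, config = config_label
    )
    message(sprintf(
      "PSA written to %s; P(cost-effective at $%.2f) = %.3f",
      out, psa$wtp, probability_ce(psa)
    ))
  } else if (command == "validate") {
    res <- report_base_case(params, out_dir = out, config = config_label)
    message("validation block included in base_case.json under ", out)
  } else if (command == "simulate") {
    if (!opts$strategy %in% strategy_names(params)) {
      usage_error(paste0("unknown strategy: ", opts$strategy))
    }
    report_microsim(params, opts$strategy,
      n = opts$n_patients, seed = opts$seed,
      out_dir = out, config = config_label
    )
    message("microsimulation written to ", out)
  }
}

tryCatch(run(), error = function(e) {
  message("error: ", conditionMessage(e))
  quit(status = 1)
})
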