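#' Default model parameters
#'
#' Loads the bundled parameter set: per-cycle event probabilities for the four
#' treatment arms (dapagliflozin, control1, empagliflozin, control2), the NYHA
#' class transition matrix, age-banded non-cardiovascular mortality, per-cycle
#' utilities, costs, run settings and the uncertain-parameter ranges used by
#' the sensitivity analyses. Probabilities are per 3-month cycle; costs are
#' 2020 USD.
#'
#' @return An object of class `hf_params`: a named list with elements
#'   `probabilities`, `noncv_mortality` (tibble of age bands),
#'   `nyha_matrix` (4x4), `utilities`, `costs`, `settings` and `specs`
#'   (tibble of uncertain-parameter ranges, one row per model input with a
#'   stated range or sampling family).
#' @export
#' @examples
#' p <- default_params()
#' p$probabilities$cv_death[["dapagliflozin"]]
default_params <- function() {
  path <- system.file("extdata", "default_params.yaml", package = "hfcea")
  if (path == "") {
    abort("bundled default_params.yaml not found; is the package installed?")
  }
  params <- parse_config(yaml::read_yaml(path))
  validate_params(params)
  params
}

#' Load a model configuration file
#'
#' Reads a YAML or JSON configuration and merges it over the bundled defaults:
#' any field omitted in the file keeps its default value. The merged set is
#' validated against the model invariants before being returned.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file whose
#'   structure mirrors the bundled `default_params.yaml`.
#' @return An `hf_params` object (see [default_params()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- yaml::read_yaml(
    system.file("extdata", "default_params.yaml", package = "hfcea")
  )
  merged <- merge_config(defaults, raw)
  params <- parse_config(merged)
  validate_params(params)
  params
}

#' Write a parameter set to a configuration file
#'
#' Serializes an `hf_params` object to YAML or JSON (by file extension) such
#' that [load_config()] reproduces an equal parameter set.
#'
#' @param params An `hf_params` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "hf_params"))
  raw <- list(
    probabilities = list(
      cv_death = as.list(params$probabilities$cv_death),
      hf_hospitalization = as.list(params$probabilities$hf_hospitalization),
      hf_readmission = params$probabilities$hf_readmission
    ),
    noncv_mortality = purrr::pmap(
      params$noncv_mortality,
      function(age_low, age_high, prob) {
        list(age_low = age_low, age_high = age_high, prob = prob)
      }
    ),
    nyha_matrix = setNames(
      lapply(seq_len(4), function(i) unname(params$nyha_matrix[i, ])),
      NYHA_STATES
    ),
    utilities = list(
      per_cycle = as.list(params$utilities$per_cycle),
      event_disutility = params$utilities$event_disutility
    ),
    costs = as.list(params$costs),
    settings = params$settings,
    ranges = purrr::pmap(
      params$specs,
      function(path, mean, low, high, distribution) {
        out <- list(path = path, distribution = distribution)
        if (is.finite(low)) out$low <- low
        if (is.finite(high)) out$high <- high
        out
      }
    )
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

# Recursive merge of a user config over the defaults. Named lists merge
# field-by-field; unnamed lists (age bands, ranges) and scalars replace
# wholesale; 'ranges' entries merge by their 'path' key.
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  if (is.null(names(defaults)) || is.null(names(user))) return(user)
  for (nm in names(user)) {
    if (nm == "ranges" && !is.null(defaults$ranges)) {
      defaults$ranges <- merge_ranges(defaults$ranges, user$ranges)
    } else if (nm %in% names(defaults)) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

merge_ranges <- function(defaults, user) {
  paths <- vapply(defaults, function(x) x$path, character(1))
  for (entry in user) {
    i <- match(entry$path, paths)
    if (is.na(i)) {
      defaults <- c(defaults, list(entry))
      paths <- c(paths, entry$path)
    } else {
      defaults[[i]] <- modifyList(defaults[[i]], entry)
    }
  }
  defaults
}

# Turn the raw (YAML-shaped) list into the typed hf_params object.
parse_config <- function(raw) {
  num_named <- function(x, who) {
    v <- unlist(x)
    if (!is.numeric(v)) abort(paste0("non-numeric values in ", who))
    v
  }
  nyha <- do.call(rbind, lapply(raw$nyha_matrix[NYHA_STATES], as.numeric))
  dimnames(nyha) <- list(NYHA_STATES, NYHA_STATES)
  specs <- purrr::map_dfr(raw$ranges, function(x) {
    tibble(
      path = x$path,
      low = if (is.null(x$low)) NA_real_ else as.numeric(x$low),
      high = if (is.null(x$high)) NA_real_ else as.numeric(x$high),
      distribution = x$distribution
    )
  })
  params <- structure(
    list(
      probabilities = list(
        cv_death = num_named(raw$probabilities$cv_death, "cv_death"),
        hf_hospitalization = num_named(
          raw$probabilities$hf_hospitalization, "hf_hospitalization"
        ),
        hf_readmission = as.numeric(raw$probabilities$hf_readmission)
      ),
      noncv_mortality = purrr::map_dfr(raw$noncv_mortality, as_tibble),
      nyha_matrix = nyha,
      utilities = list(
        per_cycle = num_named(raw$utilities$per_cycle, "utilities")[NYHA_STATES],
        event_disutility = as.numeric(raw$utilities$event_disutility)
      ),
      costs = num_named(raw$costs, "costs"),
      settings = raw$settings
    ),
    class = "hf_params"
  )
  params$settings$initial_distribution <-
    as.numeric(params$settings$initial_distribution)
  # spec means live alongside the ranges so each row is self-contained
  params$specs <- dplyr::mutate(
    specs,
    mean = purrr::map_dbl(.data$path, ~ param_get(params, .x, row_mean = TRUE)),
    .after = "path"
  )
  params
}

#' Strategy names defined by a parameter set
#'
#' @param params An `hf_params` object.
#' @return Character vector of arm names.
#' @export
strategy_names <- function(params) names(params$probabilities$cv_death)

#' Trial-matched strategy pairs
#'
#' The two comparisons evaluated by the model: each SGLT2 inhibitor arm
#' against the control arm of its own source trial.
#'
#' @return Named list of length-2 character vectors
#'   `c(intervention, control)`.
#' @export
strategy_pairs <- function() {
  list(
    dapa = c("dapagliflozin", "control1"),
    empa = c("empagliflozin", "control2")
  )
}

#' Assemble the per-arm parameter row for one strategy
#'
#' Combines the arm-specific event probabilities and drug cost with the shared
#' standard-treatment cost, hospitalization cost and readmission probability.
#' Control arms carry a zero drug cost.
#'
#' @param params An `hf_params` object.
#' @param strategy Arm name, one of [strategy_names()].
#' @return One-row tibble with columns `name`, `cv_death_per_cycle`,
#'   `hosp_per_cycle`, `readmit_per_hosp`, `drug_cost_per_cycle`,
#'   `standard_cost_per_cycle`, `hosp_cost_per_event`.
#' @export
strategy_params <- function(params, strategy) {
  if (!strategy %in% strategy_names(params)) {
    abort(paste0(
      "unknown strategy '", strategy, "'; available: ",
      paste(strategy_names(params), collapse = ", ")
    ))
  }
  drug <- if (strategy %in% names(params$costs)) {
    params$costs[[strategy]]
  } else {
    0
  }
  tibble(
    name = strategy,
    cv_death_per_cycle = params$probabilities$cv_death[[strategy]],
    hosp_per_cycle = params$probabilities$hf_hospitalization[[strategy]],
    readmit_per_hosp = params$probabilities$hf_readmission,
    drug_cost_per_cycle = drug,
    standard_cost_per_cycle = params$costs[["standard"]],
    hosp_cost_per_event = params$costs[["hospitalization"]]
  )
}

#' Read or replace one model input by path
#'
#' Dot-separated paths address individual inputs, e.g.
#' `"cv_death.dapagliflozin"`, `"hf_hospitalization.control2"`,
#' `"hf_readmission"`, `"utility.NYHA3"`, `"event_disutility"`,
#' `"cost.standard"`, `"nyha.NYHA2"` (a transition-matrix row),
#' `"discount"`, `"horizon"`. These are the paths used by the
#' sensitivity-analysis range table and by scenario overrides.
#'
#' @param params An `hf_params` object.
#' @param path Parameter path string.
#' @param row_mean For matrix-row paths, return `NA` (rows have no scalar
#'   mean) instead of the row vector; internal use.
#' @return `param_get()`: the current value. `param_set()`: a modified copy
#'   of `params` (the input is never mutated).
#' @export
param_get <- function(params, path, row_mean = FALSE) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  key <- if (length(parts) > 1) parts[2] else NULL
  switch(head,
    cv_death = params$probabilities$cv_death[[key]],
    hf_hospitalization = params$probabilities$hf_hospitalization[[key]],
    hf_readmission = params$probabilities$hf_readmission,
    utility = params$utilities$per_cycle[[key]],
    event_disutility = params$utilities$event_disutility,
    cost = params$costs[[key]],
    discount = params$settings$annual_discount,
    horizon = params$settings$horizon,
    nyha = if (row_mean) NA_real_ else params$nyha_matrix[key, ],
    abort(paste0("unknown parameter path: ", path))
  )
}

#' @rdname param_get
#' @param value Replacement value (a length-4 probability vector for
#'   `nyha.*` paths, a scalar otherwise).
#' @export
param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  key <- if (length(parts) > 1) parts[2] else NULL
  bad_key <- function(pool) {
    if (is.null(key) || !key %in% pool) {
      abort(paste0("unknown parameter path: ", path))
    }
  }
  switch(head,
    cv_death = {
      bad_key(strategy_names(params))
      params$probabilities$cv_death[[key]] <- value
    },
    hf_hospitalization = {
      bad_key(strategy_names(params))
      params$probabilities$hf_hospitalization[[key]] <- value
    },
    hf_readmission = params$probabilities$hf_readmission <- value,
    utility = {
      bad_key(NYHA_STATES)
      params$utilities$per_cycle[[key]] <- value
    },
    event_disutility = params$utilities$event_disutility <- value,
    cost = {
      bad_key(names(params$costs))
      params$costs[[key]] <- value
    },
    discount = params$settings$annual_discount <- value,
    horizon = params$settings$horizon <- value,
    nyha = {
      bad_key(NYHA_STATES)
      stopifnot(length(value) == 4)
      params$nyha_matrix[key, ] <- value
    },
    abort(paste0("unknown parameter path: ", path))
  )
  params
}

#' Validate a parameter set against the model invariants
#'
#' Checks probability bounds, transition-matrix row sums, the initial NYHA
#' distribution, utility ordering, cost signs, horizon/cycle compatibility and
#' the contiguity of the non-CV mortality age bands. Violations raise an error
#' naming the offending field.
#'
#' @param params An `hf_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  chk_prob <- function(x, who) {
    bad <- !is.finite(x) | x < 0 | x > 1
    if (any(bad)) {
      abort(paste0(
        "probabilities out of [0,1] in ", who, ": ",
        paste(names(x)[bad], collapse = ", ")
      ))
    }
  }
  chk_prob(params$probabilities$cv_death, "cv_death")
  chk_prob(params$probabilities$hf_hospitalization, "hf_hospitalization")
  chk_prob(params$probabilities$hf_readmission, "hf_readmission")
  chk_prob(params$noncv_mortality$prob, "noncv_mortality")
  if (any(params$costs < 0)) abort("costs must be non-negative")

  u <- params$utilities$per_cycle
  chk_prob(u, "utilities")
  if (any(diff(u) > 1e-12)) {
    abort("per-cycle utilities must be non-increasing from NYHA1 to NYHA4")
  }
  if (params$utilities$event_disutility > 0) {
    abort("event_disutility must be <= 0")
  }

  m <- params$nyha_matrix
  if (any(m < 0 | m > 1)) abort("nyha_matrix entries must lie in [0,1]")
  sums <- rowSums(m)
  off <- abs(sums - 1) > 1e-9
  if (any(off)) {
    i <- which(off)[1]
    abort(sprintf(
      "nyha_matrix row %s sums to %.6f, expected 1", NYHA_STATES[i], sums[i]
    ))
  }

  init <- params$settings$initial_distribution
  if (length(init) != 4 || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    abort(sprintf(
      "initial_distribution must be 4 non-negative entries summing to 1 (sum = %.6f)",
      sum(init)
    ))
  }

  s <- params$settings
  ncyc <- s$horizon / s$cycle_length
  if (s$horizon < 0 || abs(ncyc - round(ncyc)) > 1e-9) {
    abort("horizon must be a non-negative integer multiple of cycle_length")
  }
  if (s$annual_discount < 0) abort("annual_discount must be >= 0")
  if (!s$discount_convention %in% c("start_of_cycle", "mid_cycle")) {
    abort("discount_convention must be 'start_of_cycle' or 'mid_cycle'")
  }

  bands <- params$noncv_mortality
  if (nrow(bands) == 0) abort("noncv_mortality table is empty")
  if (is.unsorted(bands$age_low) ||
      any(bands$age_low[-1] != bands$age_high[-nrow(bands)] + 1)) {
    abort("noncv_mortality age bands must be contiguous and non-overlapping")
  }

  bad <- with(
    params$specs,
    is.finite(low) & is.finite(high) &
      distribution %in% c("beta", "gamma") &
      !(low <= mean + 1e-12 & mean <= high + 1e-12)
  )
  if (any(bad)) {
    warn(paste0(
      "range does not bracket the mean for: ",
      paste(params$specs$path[bad], collapse = ", ")
    ))
  }
  invisible(params)
}

#' @export
print.hf_params <- function(x, ...) {
  s <- x$settings
  cat("<hf_params>\n")
  cat(
    "  strategies:", paste(strategy_names(x), collapse = ", "), "\n",
    sprintf(
      " settings: start age %g, %g cycles of %g y, discount %g%%/y, WTP $%.2f/QALY\n",
      s$start_age, s$horizon / s$cycle_length, s$cycle_length,
      100 * s$annual_discount, s$wtp_per_qaly
    ),
    sprintf(
      " conventions: half-cycle correction %s, %s discounting, non-CV mortality %s\n",
      if (isTRUE(s$half_cycle_correction)) "on" else "off",
      s$discount_convention,
      if (isTRUE(s$noncv_mortality_is_annual)) "annual" else "per-cycle"
    ),
    " uncertain parameters:", nrow(x$specs), "\n"
  )
  invisible(x)
}
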