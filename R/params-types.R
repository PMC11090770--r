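#' An uncertain model parameter with base value and plausible bounds
#'
#' Every model input that is varied in sensitivity analysis is stored as a
#' base value plus (low, high) bounds and a sampling-family tag
#' (`"beta"` for quantities bounded in \[0, 1\], `"gamma"` for
#' non-negative quantities).  `low == base == high` denotes a fixed value.
#'
#' @param base Base-case value.
#' @param low,high Plausible bounds; defaults fix the parameter.
#' @param family `"beta"` or `"gamma"`.
#' @param provenance Free-text provenance tag; fixture values that are
#'   round-number stand-ins (not published figures) carry `"placeholder"`.
#' @return Object of class `param_value`.
#' @export
param_value <- function(base, low = base, high = base,
                        family = c("gamma", "beta"),
                        provenance = "unspecified") {
  family <- match.arg(family)
  if (!is.finite(base) || !is.finite(low) || !is.finite(high)) {
    stop("param_value entries must be finite", call. = FALSE)
  }
  if (!(low <= base && base <= high)) {
    stop(sprintf("need low <= base <= high, got (%.6g, %.6g, %.6g)",
                 low, base, high), call. = FALSE)
  }
  if (family == "beta" && (low < 0 || high > 1)) {
    stop("beta-family parameters must lie in [0, 1]", call. = FALSE)
  }
  if (family == "gamma" && low < 0) {
    stop("gamma-family parameters must be non-negative", call. = FALSE)
  }
  structure(list(base = base, low = low, high = high, family = family,
                 provenance = provenance),
            class = "param_value")
}

#' @export
print.param_value <- function(x, ...) {
  cat(sprintf("<param %s: %.6g [%.6g, %.6g] (%s)>\n",
              x$family, x$base, x$low, x$high, x$provenance))
  invisible(x)
}

#' Define a stent strategy
#'
#' @param name Strategy label, e.g. `"Resonance"` or `"JJ"`.
#' @param planned_exchange_interval Months between scheduled stent
#'   changes (integer >= 1): 12 for the metallic stent, 6 for
#'   polyurethane JJ, per instructions for use and UK practice.
#' @param stent_unit_cost Device price in GBP, as a [param_value()].
#' @param insertion_minutes Theatre time for first insertion, as a
#'   [param_value()] (minutes).
#' @param replacement_minutes Theatre time for an exchange; by default
#'   insertion time plus 10 minutes.
#' @return Object of class `stent_strategy`.
#' @export
stent_strategy <- function(name, planned_exchange_interval,
                           stent_unit_cost, insertion_minutes,
                           replacement_minutes = NULL) {
  k <- planned_exchange_interval
  if (!is.finite(k) || k < 1 || k != round(k)) {
    stop("`planned_exchange_interval` must be an integer number of months >= 1",
         call. = FALSE)
  }
  if (is.numeric(stent_unit_cost)) stent_unit_cost <- param_value(stent_unit_cost)
  if (is.numeric(insertion_minutes)) insertion_minutes <- param_value(insertion_minutes)
  if (is.null(replacement_minutes)) {
    replacement_minutes <- param_value(
      insertion_minutes$base + 10,
      insertion_minutes$low + 10, insertion_minutes$high + 10,
      provenance = "insertion + 10 min")
  }
  if (is.numeric(replacement_minutes)) replacement_minutes <- param_value(replacement_minutes)
  if (insertion_minutes$base <= 0 || replacement_minutes$base <= 0) {
    stop("procedure minutes must be positive", call. = FALSE)
  }
  if (stent_unit_cost$base < 0) stop("stent cost must be >= 0", call. = FALSE)
  structure(list(name = name,
                 planned_exchange_interval = as.integer(k),
                 stent_unit_cost = stent_unit_cost,
                 insertion_minutes = insertion_minutes,
                 replacement_minutes = replacement_minutes),
            class = "stent_strategy")
}

#' Global model settings
#'
#' @param horizon Time horizon in monthly cycles (positive multiple of 12).
#' @param discount_rate_annual Annual discount rate for costs and
#'   benefits (UK reference case 3.5%).
#' @param wtp Willingness-to-pay threshold, GBP per QALY.
#' @param half_cycle_correction Apply trapezoidal half-cycle correction
#'   to state-occupancy accrual.
#' @param reporting_horizons Months at which cumulative results are
#'   reported.
#' @param daycase_fraction Share of procedures recovered as day cases, as
#'   a [param_value()]; the remainder incur an overnight stay. Varied in
#'   deterministic sensitivity analysis only.
#' @return Object of class `model_settings`.
#' @export
model_settings <- function(horizon = 60L,
                           discount_rate_annual = 0.035,
                           wtp = 20000,
                           half_cycle_correction = TRUE,
                           reporting_horizons = c(12L, 24L, 36L, 60L),
                           daycase_fraction = param_value(1, 0.75, 1,
                                                          family = "beta")) {
  if (!is.finite(horizon) || horizon < 12 || horizon %% 12 != 0) {
    stop("`horizon` must be a positive multiple of 12 months", call. = FALSE)
  }
  if (discount_rate_annual < 0) {
    stop("`discount_rate_annual` must be >= 0", call. = FALSE)
  }
  if (is.numeric(daycase_fraction)) {
    daycase_fraction <- param_value(daycase_fraction, family = "beta")
  }
  if (any(reporting_horizons > horizon)) {
    stop("reporting horizons must not exceed the model horizon", call. = FALSE)
  }
  structure(list(cycle_length = 1L,
                 horizon = as.integer(horizon),
                 discount_rate_annual = discount_rate_annual,
                 wtp = wtp,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 reporting_horizons = as.integer(reporting_horizons),
                 daycase_fraction = daycase_fraction),
            class = "model_settings")
}

pv_names <- c("base", "low", "high", "family")

as_pv <- function(x, path) {
  if (inherits(x, "param_value")) return(x)
  if (!is.list(x) || is.null(x$base)) {
    stop(sprintf("%s: expected {base, low, high, family}", path),
         call. = FALSE)
  }
  tryCatch(
    param_value(x$base,
                if (is.null(x$low)) x$base else x$low,
                if (is.null(x$high)) x$base else x$high,
                family = if (is.null(x$family)) "gamma" else x$family,
                provenance = if (is.null(x$provenance)) "unspecified" else x$provenance),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}

#' Bundle all model inputs
#'
#' The single object every analysis consumes: settings, the two stent
#' strategies, clinical transition probabilities, annual state utilities
#' and unit costs.  Construction validates probability ranges and the
#' competing-transition mass constraint.
#'
#' @param settings A [model_settings()].
#' @param strategies Named list of two [stent_strategy()] objects; the
#'   first is the intervention, the second the comparator (increments are
#'   first minus second).
#' @param clinical Named list: `p_death`, `p_uti_resolve` (shared), and
#'   per-strategy lists with `p_fail`, `p_uti`, all [param_value()]s with
#'   `family = "beta"`.
#' @param utilities Named list of annual utilities `u_patent`, `u_uti`,
#'   `u_failed` ([param_value()]s). Monthly utility is annual / 12.
#' @param costs Named list of unit costs ([param_value()]s), see
#'   [base_case_fixture()] for the full set of keys.
#' @return Object of class `cua_inputs`.
#' @export
cua_inputs <- function(settings, strategies, clinical, utilities, costs) {
  inputs <- structure(list(settings = settings, strategies = strategies,
                           clinical = clinical, utilities = utilities,
                           costs = costs),
                      class = "cua_inputs")
  validate_inputs(inputs)
  inputs
}

required_cost_keys <- c(
  "theatre_per_minute", "surgeon_per_minute", "nurse_band6_per_minute",
  "nurse_band5_per_minute", "consumables_per_procedure",
  "bed_stay_per_hour", "overnight_stay", "imaging_per_procedure",
  "gp_visit", "antibiotic_course", "oncology_outpatient_visit")

#' Validate a `cua_inputs` bundle
#'
#' Checks structural completeness, probability ranges, bound ordering and
#' the within-state competing-transition mass constraint
#' (`p_fail + p_uti + p_death <= 1`).  Errors name the offending entry.
#'
#' @param inputs A `cua_inputs` object (or plain list with the same shape).
#' @return `inputs`, invisibly, on success.
#' @export
validate_inputs <- function(inputs) {
  problems <- character()
  need <- function(cond, msg) if (!cond) problems <<- c(problems, msg)

  need(inherits(inputs$settings, "model_settings"),
       "settings: not a model_settings object")
  need(length(inputs$strategies) == 2,
       "strategies: exactly two strategies are required")
  for (s in inputs$strategies) {
    need(inherits(s, "stent_strategy"),
         "strategies: entries must be stent_strategy objects")
  }
  strat_names <- vapply(inputs$strategies, function(s) s$name, "")
  need(!anyDuplicated(strat_names), "strategies: names must be distinct")

  check_prob <- function(pv, path) {
    need(inherits(pv, "param_value"), sprintf("%s: missing", path))
    if (inherits(pv, "param_value")) {
      need(pv$base >= 0 && pv$base <= 1 && pv$high <= 1,
           sprintf("%s: probability and bounds must lie in [0, 1]", path))
    }
  }
  check_prob(inputs$clinical$p_death, "clinical.p_death")
  check_prob(inputs$clinical$p_uti_resolve, "clinical.p_uti_resolve")
  for (nm in strat_names) {
    blk <- inputs$clinical$by_strategy[[nm]]
    need(is.list(blk), sprintf("clinical.by_strategy.%s: missing block", nm))
    if (is.list(blk)) {
      check_prob(blk$p_fail, sprintf("clinical.by_strategy.%s.p_fail", nm))
      check_prob(blk$p_uti, sprintf("clinical.by_strategy.%s.p_uti", nm))
      if (inherits(blk$p_fail, "param_value") &&
          inherits(blk$p_uti, "param_value") &&
          inherits(inputs$clinical$p_death, "param_value")) {
        mass <- blk$p_fail$base + blk$p_uti$base + inputs$clinical$p_death$base
        need(mass <= 1, sprintf(
          "clinical.by_strategy.%s: p_fail + p_uti + p_death = %.4f exceeds 1",
          nm, mass))
      }
    }
  }
  for (nm in c("u_patent", "u_uti", "u_failed")) {
    pv <- inputs$utilities[[nm]]
    need(inherits(pv, "param_value"), sprintf("utilities.%s: missing", nm))
    if (inherits(pv, "param_value")) {
      need(pv$base >= -1 && pv$base <= 1,
           sprintf("utilities.%s: annual utility must lie in [-1, 1]", nm))
    }
  }
  for (nm in required_cost_keys) {
    pv <- inputs$costs[[nm]]
    need(inherits(pv, "param_value"), sprintf("costs.%s: missing", nm))
    if (inherits(pv, "param_value")) {
      need(pv$base >= 0, sprintf("costs.%s: must be >= 0", nm))
    }
  }
  if (length(problems)) {
    stop("invalid model inputs:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(inputs)
}

#' @export
print.cua_inputs <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<cua_inputs: %d-month horizon, %.1f%% discount, WTP %s/QALY>\n",
    s$horizon, 100 * s$discount_rate_annual, format(s$wtp, big.mark = ",")))
  for (st in x$strategies) {
    blk <- x$clinical$by_strategy[[st$name]]
    cat(sprintf(
      "  %-10s exchange every %2d mo, p_fail %.4f, p_uti %.4f, stent cost %.2f\n",
      st$name, st$planned_exchange_interval, blk$p_fail$base, blk$p_uti$base,
      st$stent_unit_cost$base))
  }
  ph <- names(Filter(function(p) identical(p$provenance, "placeholder"),
                     flatten_params(x)))
  if (length(ph)) {
    cat(sprintf("  %d placeholder-valued parameter(s); see provenance tags\n",
                length(ph)))
  }
  invisible(x)
}

# ---- parameter addressing ---------------------------------------------

#' Flatten the uncertain parameters of an input bundle
#'
#' Returns a named list of every [param_value()] in the bundle, keyed by a
#' dotted path such as `"clinical.JJ.p_fail"`,
#' `"strategies.Resonance.stent_unit_cost"`, `"utilities.u_patent"`,
#' `"costs.gp_visit"` or `"settings.daycase_fraction"`.  These paths are
#' the parameter names used by [dsa_univariate()], [psa_run()] and
#' [scenario_apply()].
#'
#' @param inputs A `cua_inputs` bundle.
#' @return Named list of `param_value` objects.
#' @export
flatten_params <- function(inputs) {
  out <- list()
  out[["clinical.p_death"]] <- inputs$clinical$p_death
  out[["clinical.p_uti_resolve"]] <- inputs$clinical$p_uti_resolve
  for (nm in names(inputs$clinical$by_strategy)) {
    blk <- inputs$clinical$by_strategy[[nm]]
    out[[paste0("clinical.", nm, ".p_fail")]] <- blk$p_fail
    out[[paste0("clinical.", nm, ".p_uti")]] <- blk$p_uti
  }
  for (nm in c("u_patent", "u_uti", "u_failed")) {
    out[[paste0("utilities.", nm)]] <- inputs$utilities[[nm]]
  }
  for (nm in names(inputs$costs)) {
    out[[paste0("costs.", nm)]] <- inputs$costs[[nm]]
  }
  for (st in inputs$strategies) {
    out[[paste0("strategies.", st$name, ".stent_unit_cost")]] <- st$stent_unit_cost
    out[[paste0("strategies.", st$name, ".insertion_minutes")]] <- st$insertion_minutes
    out[[paste0("strategies.", st$name, ".replacement_minutes")]] <- st$replacement_minutes
  }
  out[["settings.daycase_fraction"]] <- inputs$settings$daycase_fraction
  out
}

#' Set the base value of one parameter by its dotted path
#'
#' @param inputs A `cua_inputs` bundle.
#' @param path Dotted parameter path as produced by [flatten_params()].
#' @param value New base value (bounds are left untouched unless the new
#'   base falls outside them, in which case they are widened to include it).
#' @return Modified `cua_inputs` bundle.
#' @export
set_param <- function(inputs, path, value) {
  repl <- function(pv) {
    param_value(value, min(pv$low, value), max(pv$high, value),
                family = pv$family, provenance = pv$provenance)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  root <- parts[1]
  strat_names <- vapply(inputs$strategies, function(s) s$name, "")
  if (root == "clinical" && length(parts) == 2) {
    if (is.null(inputs$clinical[[parts[2]]])) stop_unknown(path)
    inputs$clinical[[parts[2]]] <- repl(inputs$clinical[[parts[2]]])
  } else if (root == "clinical" && length(parts) == 3) {
    if (is.null(inputs$clinical$by_strategy[[parts[2]]][[parts[3]]])) stop_unknown(path)
    inputs$clinical$by_strategy[[parts[2]]][[parts[3]]] <-
      repl(inputs$clinical$by_strategy[[parts[2]]][[parts[3]]])
  } else if (root == "utilities" && length(parts) == 2) {
    if (is.null(inputs$utilities[[parts[2]]])) stop_unknown(path)
    inputs$utilities[[parts[2]]] <- repl(inputs$utilities[[parts[2]]])
  } else if (root == "costs" && length(parts) == 2) {
    if (is.null(inputs$costs[[parts[2]]])) stop_unknown(path)
    inputs$costs[[parts[2]]] <- repl(inputs$costs[[parts[2]]])
  } else if (root == "strategies" && length(parts) == 3) {
    i <- match(parts[2], strat_names)
    if (is.na(i) || is.null(inputs$strategies[[i]][[parts[3]]])) stop_unknown(path)
    inputs$strategies[[i]][[parts[3]]] <- repl(inputs$strategies[[i]][[parts[3]]])
  } else if (root == "settings" && length(parts) == 2) {
    if (is.null(inputs$settings[[parts[2]]])) stop_unknown(path)
    inputs$settings[[parts[2]]] <- repl(inputs$settings[[parts[2]]])
  } else {
    stop_unknown(path)
  }
  inputs
}

stop_unknown <- function(path) {
  stop("unknown parameter path: ", path, call. = FALSE)
}

#' Get one parameter by its dotted path
#'
#' @inheritParams set_param
#' @return The `param_value` at `path`.
#' @export
get_param <- function(inputs, path) {
  all <- flatten_params(inputs)
  if (is.null(all[[path]])) stop_unknown(path)
  all[[path]]
}

# ---- file I/O ----------------------------------------------------------

pv_to_list <- function(pv) {
  list(base = pv$base, low = pv$low, high = pv$high, family = pv$family,
       provenance = pv$provenance)
}

#' Write an input bundle to YAML or JSON
#'
#' The on-disk document mirrors the in-memory structure: `settings`, a
#' `strategies` list, `clinical`, `utilities` and `costs` blocks, with
#' every uncertain value as `{base, low, high, family, provenance}`.
#' Format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param inputs A `cua_inputs` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  doc <- list(
    settings = list(
      cycle_length_months = inputs$settings$cycle_length,
      horizon_months = inputs$settings$horizon,
      discount_rate_annual = inputs$settings$discount_rate_annual,
      wtp_per_qaly = inputs$settings$wtp,
      half_cycle_correction = inputs$settings$half_cycle_correction,
      reporting_horizons_months = inputs$settings$reporting_horizons,
      daycase_fraction = pv_to_list(inputs$settings$daycase_fraction)),
    strategies = lapply(inputs$strategies, function(s) list(
      name = s$name,
      planned_exchange_interval_months = s$planned_exchange_interval,
      stent_unit_cost_gbp = pv_to_list(s$stent_unit_cost),
      insertion_minutes = pv_to_list(s$insertion_minutes),
      replacement_minutes = pv_to_list(s$replacement_minutes))),
    clinical = c(
      list(p_death = pv_to_list(inputs$clinical$p_death),
           p_uti_resolve = pv_to_list(inputs$clinical$p_uti_resolve)),
      list(by_strategy = lapply(inputs$clinical$by_strategy, function(b)
        list(p_fail = pv_to_list(b$p_fail), p_uti = pv_to_list(b$p_uti))))),
    utilities = lapply(inputs$utilities, pv_to_list),
    costs = lapply(inputs$costs, pv_to_list))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

#' Read an input bundle from YAML or JSON
#'
#' Inverse of [write_inputs()].  The document is schema-checked on load;
#' malformed entries are reported with their dotted path.
#'
#' @param path Input file path (`.yaml`, `.yml` or `.json`).
#' @return A validated `cua_inputs` bundle.
#' @export
read_inputs <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (blk in c("settings", "strategies", "clinical", "utilities", "costs")) {
    if (is.null(doc[[blk]])) {
      stop(sprintf("%s: missing top-level block", blk), call. = FALSE)
    }
  }
  st <- doc$settings
  settings <- model_settings(
    horizon = st$horizon_months,
    discount_rate_annual = st$discount_rate_annual,
    wtp = st$wtp_per_qaly,
    half_cycle_correction = st$half_cycle_correction,
    reporting_horizons = unlist(st$reporting_horizons_months),
    daycase_fraction = as_pv(st$daycase_fraction, "settings.daycase_fraction"))
  strategies <- lapply(doc$strategies, function(s) stent_strategy(
    name = s$name,
    planned_exchange_interval = s$planned_exchange_interval_months,
    stent_unit_cost = as_pv(s$stent_unit_cost_gbp,
                            paste0("strategies.", s$name, ".stent_unit_cost_gbp")),
    insertion_minutes = as_pv(s$insertion_minutes,
                              paste0("strategies.", s$name, ".insertion_minutes")),
    replacement_minutes = as_pv(s$replacement_minutes,
                                paste0("strategies.", s$name, ".replacement_minutes"))))
  names(strategies) <- vapply(strategies, function(s) s$name, "")
  clinical <- list(
    p_death = as_pv(doc$clinical$p_death, "clinical.p_death"),
    p_uti_resolve = as_pv(doc$clinical$p_uti_resolve, "clinical.p_uti_resolve"),
    by_strategy = lapply(stats::setNames(names(doc$clinical$by_strategy),
                                         names(doc$clinical$by_strategy)),
                         function(nm) {
      b <- doc$clinical$by_strategy[[nm]]
      list(p_fail = as_pv(b$p_fail, paste0("clinical.by_strategy.", nm, ".p_fail")),
           p_uti = as_pv(b$p_uti, paste0("clinical.by_strategy.", nm, ".p_uti")))
    }))
  utilities <- lapply(stats::setNames(names(doc$utilities), names(doc$utilities)),
                      function(nm) as_pv(doc$utilities[[nm]],
                                         paste0("utilities.", nm)))
  costs <- lapply(stats::setNames(names(doc$costs), names(doc$costs)),
                  function(nm) as_pv(doc$costs[[nm]], paste0("costs.", nm)))
  cua_inputs(settings, strategies, clinical, utilities, costs)
}
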