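#' Evaluate the model with a set of parameter values
#'
#' Applies named base-value overrides (dotted parameter paths, see
#' [flatten_params()]) and runs the full two-strategy comparison.
#' The workhorse behind deterministic and probabilistic sensitivity
#' analysis and scenario analysis.
#'
#' @param inputs A [cua_inputs()] bundle.
#' @param values Named numeric vector or list of parameter overrides.
#' @return A `cua_outcomes` data frame (see [compare_strategies()]).
#' @export
evaluate_at <- function(inputs, values = NULL) {
  if (length(values)) {
    for (nm in names(values)) {
      inputs <- set_param(inputs, nm, as.numeric(values[[nm]]))
    }
  }
  compare_strategies(inputs)
}

#' One univariate sensitivity sweep
#'
#' Re-runs the full model twice with a single parameter at each of its
#' limits, everything else at base, and records the incremental cost and
#' net monetary benefit at the reporting horizon.
#'
#' @param inputs A [cua_inputs()] bundle.
#' @param parameter Dotted parameter path (see [flatten_params()]).
#' @param low,high Sweep limits; default to the parameter's stored bounds.
#' @param horizon Reporting horizon in months (default: the largest).
#' @return One-row data frame: parameter, limits, incremental cost and
#'   NMB at each limit, and the absolute swings.
#' @export
univariate_sweep <- function(inputs, parameter, low = NULL, high = NULL,
                             horizon = max(inputs$settings$reporting_horizons)) {
  pv <- get_param(inputs, parameter)  # errors on unknown parameter
  if (is.null(low)) low <- pv$low
  if (is.null(high)) high <- pv$high
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  at <- function(value) {
    out <- evaluate_at(inputs, stats::setNames(list(value), parameter))
    out[out$horizon == horizon, c("delta_cost", "nmb")]
  }
  lo <- at(low); hi <- at(high)
  data.frame(parameter = parameter, low = low, high = high,
             delta_cost_low = lo$delta_cost, delta_cost_high = hi$delta_cost,
             delta_cost_swing = abs(hi$delta_cost - lo$delta_cost),
             nmb_low = lo$nmb, nmb_high = hi$nmb,
             nmb_swing = abs(hi$nmb - lo$nmb))
}

#' Deterministic (tornado) sensitivity analysis
#'
#' Sweeps every parameter with distinct bounds one at a time over
#' (low, high) and tabulates the impact on incremental cost and net
#' monetary benefit.  Entries are sorted by descending incremental-cost
#' swing, alphabetically on ties.
#'
#' @inheritParams univariate_sweep
#' @param parameters Character vector of dotted paths; defaults to every
#'   parameter whose bounds differ.
#' @return A `cua_tornado` data frame (one row per parameter) with the
#'   base-case `delta_cost` and `nmb` at the chosen horizon as
#'   attributes.
#' @export
dsa_univariate <- function(inputs, parameters = NULL,
                           horizon = max(inputs$settings$reporting_horizons)) {
  all_params <- flatten_params(inputs)
  if (is.null(parameters)) {
    parameters <- names(Filter(function(pv) pv$high > pv$low, all_params))
  }
  rows <- lapply(parameters, function(p)
    univariate_sweep(inputs, p, horizon = horizon))
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_cost_swing, out$parameter), ]
  rownames(out) <- NULL
  base <- compare_strategies(inputs)
  base <- base[base$horizon == horizon, ]
  attr(out, "base_delta_cost") <- base$delta_cost
  attr(out, "base_nmb") <- base$nmb
  attr(out, "horizon") <- horizon
  class(out) <- c("cua_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent joint samples of every uncertain parameter from
#' its moment-matched distribution (beta for probabilities and
#' utilities, gamma for costs and resource use; see [fit_param_dist()]),
#' re-runs the full model per draw, and records the incremental cost and
#' QALYs.  Parameters are sampled independently (no correlation
#' structure).  A draw whose probabilities compose to more than 1 within
#' a state's competing transitions is rejected and redrawn; the number
#' of rejections is reported.
#'
#' @param inputs A [cua_inputs()] bundle.
#' @param n Number of Monte-Carlo iterations (>= 1).
#' @param seed Integer seed; a fixed seed reproduces the sample set.
#' @param spread Bound interpretation passed to [fit_param_dist()].
#' @param exclude Parameter paths to hold fixed; by default the
#'   day-case/overnight mix, which is a deterministic-analysis bound
#'   rather than a sampling distribution.
#' @param horizon Reporting horizon for the recorded increments.
#' @return A `cua_psa` object: list with `samples` (data frame, one row
#'   per draw: draw index, every sampled parameter, `delta_cost`,
#'   `delta_qalys`, `nmb`), `rejections`, `horizon`, `wtp` and the
#'   deterministic `base` outcomes row.
#' @export
psa_run <- function(inputs, n, seed, spread = c("ci95", "range2"),
                    exclude = "settings.daycase_fraction",
                    horizon = max(inputs$settings$reporting_horizons)) {
  spread <- match.arg(spread)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  params <- flatten_params(inputs)
  params <- params[setdiff(names(params), exclude)]
  specs <- lapply(stats::setNames(names(params), names(params)), function(nm) {
    tryCatch(fit_param_dist(params[[nm]], spread = spread),
             error = function(e) stop(sprintf(
               "cannot fit a sampling distribution for %s: %s",
               nm, conditionMessage(e)), call. = FALSE))
  })
  strat_names <- vapply(inputs$strategies, function(s) s$name, "")
  draw_valid <- function() {
    repeat {
      draw <- vapply(specs, sample_dist, numeric(1))
      ok <- TRUE
      for (nm in strat_names) {
        mass <- draw[[paste0("clinical.", nm, ".p_fail")]] +
          draw[[paste0("clinical.", nm, ".p_uti")]] +
          draw[["clinical.p_death"]]
        if (mass > 1) ok <- FALSE
      }
      if (ok) return(draw)
      rejections <<- rejections + 1L
    }
  }
  set.seed(seed)
  rejections <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    draw <- draw_valid()
    out <- evaluate_at(inputs, draw)
    out <- out[out$horizon == horizon, ]
    rows[[i]] <- c(draw = i, draw, delta_cost = out$delta_cost,
                   delta_qalys = out$delta_qalys, nmb = out$nmb)
  }
  samples <- as.data.frame(do.call(rbind, rows))
  base <- compare_strategies(inputs)
  structure(list(samples = samples, rejections = rejections,
                 horizon = horizon, wtp = inputs$settings$wtp,
                 base = base[base$horizon == horizon, ]),
            class = "cua_psa")
}

#' @export
print.cua_psa <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<cua_psa: %d draws at %d months; mean dC %.2f, mean dQ %.4f; %d redraw(s)>\n",
    nrow(s), x$horizon, mean(s$delta_cost), mean(s$delta_qalys),
    x$rejections))
  cat(sprintf("  P(cost-effective at WTP %s) = %.3f\n",
              format(x$wtp, big.mark = ","),
              mean(nmb(s$delta_cost, s$delta_qalys, x$wtp) > 0)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the
#' intervention is cost-effective: the fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param psa A `cua_psa` from [psa_run()] (or a data frame with
#'   `delta_cost` and `delta_qalys` columns).
#' @param wtp_grid Willingness-to-pay grid in GBP/QALY; the default
#'   covers 0 to 50,000 in steps of 1,000.
#' @return Data frame with columns `wtp` and `p_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(wtp_grid) == 0) stop("`wtp_grid` must be non-empty", call. = FALSE)
  s <- if (inherits(psa, "cua_psa")) psa$samples else psa
  if (NROW(s) == 0) stop("no PSA samples supplied", call. = FALSE)
  p <- vapply(wtp_grid, function(w)
    mean(nmb(s$delta_cost, s$delta_qalys, w) > 0), numeric(1))
  data.frame(wtp = wtp_grid, p_cost_effective = p)
}

#' Scenario analysis
#'
#' Re-runs the full comparison under a named set of parameter
#' overrides -- for instance alternative insertion and replacement
#' theatre times.  Overrides that touch only cost-side parameters leave
#' the clinical trace, and hence QALYs and stent counts, bit-identical
#' to the base case.
#'
#' @param inputs A [cua_inputs()] bundle.
#' @param overrides Named list/vector of dotted parameter paths to new
#'   base values; unknown paths are rejected.
#' @return A `cua_outcomes` data frame under the scenario.
#' @export
scenario_apply <- function(inputs, overrides = list()) {
  evaluate_at(inputs, overrides)
}

#' Alternative procedure-time scenario
#'
#' The named scenario explored alongside the base case: insertion times
#' of 37.5 min (Resonance) and 22.5 min (JJ) and replacement times of
#' 67.5 and 52.5 min, as used by earlier models in this therapy area.
#'
#' @return Named list of overrides for [scenario_apply()].
#' @export
scenario_procedure_times <- function() {
  list("strategies.Resonance.insertion_minutes" = 37.5,
       "strategies.JJ.insertion_minutes" = 22.5,
       "strategies.Resonance.replacement_minutes" = 67.5,
       "strategies.JJ.replacement_minutes" = 52.5)
}

#' Named input presets
#'
#' Documented variants of the base case:
#' * `"death_pm10"`: mortality sensitivity bounds narrowed to +/-10%
#'   of base (the narrower of the two published variation statements).
#' * `"uti_shared"`: the comparator's infection probability set equal to
#'   the intervention's (the assumption variant, in place of the two
#'   separately tabulated rates).
#'
#' @param inputs A [cua_inputs()] bundle.
#' @param preset One of `"death_pm10"`, `"uti_shared"`.
#' @return Modified `cua_inputs` bundle.
#' @export
apply_preset <- function(inputs, preset = c("death_pm10", "uti_shared")) {
  preset <- match.arg(preset)
  if (preset == "death_pm10") {
    d <- inputs$clinical$p_death
    inputs$clinical$p_death <- param_value(
      d$base, d$base * 0.9, min(d$base * 1.1, 1), family = "beta",
      provenance = d$provenance)
  } else {
    nms <- vapply(inputs$strategies, function(s) s$name, "")
    ref <- inputs$clinical$by_strategy[[nms[1]]]$p_uti
    inputs$clinical$by_strategy[[nms[2]]]$p_uti <- ref
  }
  inputs
}
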