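#' Discount factor for a monthly cycle
#'
#' Continuous-per-cycle convention: `(1 + annual_rate)^(-cycle / 12)`,
#' so discounting accrues smoothly within each year of monthly cycles.
#'
#' @param cycle Month index (0 = model start).
#' @param annual_rate Annual discount rate (e.g. 0.035).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) stop("`cycle` must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

# scalar base values of all unit costs, for fast repeated accrual
cost_base <- function(inputs) {
  vapply(inputs$costs, function(pv) pv$base, numeric(1))
}

#' Bottom-up cost of a stent procedure
#'
#' Sums theatre time (theatre running plus surgeon cost per minute over
#' the procedure's minutes), consumables, the stent itself, and
#' post-procedure recovery.  Day-case recovery comprises a 4-hour bed
#' stay, 30 minutes of one-to-one band-6 nursing and 240 minutes of
#' band-5 nursing shared across four patients; the `(1 - daycase_fraction)`
#' share of patients instead incur an overnight stay.  An unplanned
#' exchange (stent failure) additionally triggers an unplanned oncology
#' outpatient visit.
#'
#' @param strategy A [stent_strategy()].
#' @param costs Named numeric vector of unit-cost base values (see
#'   [base_case_fixture()] for keys) or a list of [param_value()]s.
#' @param kind One of `"insertion"`, `"planned_exchange"`,
#'   `"unplanned_exchange"`.
#' @param daycase_fraction Proportion of procedures recovered as day
#'   cases, in `[0, 1]`.
#' @param minutes Optional override of procedure minutes (used by the
#'   sensitivity machinery); defaults to the strategy's insertion or
#'   replacement minutes.
#' @param stent_cost Optional override of the stent unit cost.
#' @return Cost in GBP.
#' @export
procedure_cost <- function(strategy, costs,
                           kind = c("insertion", "planned_exchange",
                                    "unplanned_exchange"),
                           daycase_fraction = 1, minutes = NULL,
                           stent_cost = NULL) {
  kind <- match.arg(kind)
  if (is.list(costs)) costs <- vapply(costs, function(pv) pv$base, numeric(1))
  if (daycase_fraction < 0 || daycase_fraction > 1) {
    stop("`daycase_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(minutes)) {
    minutes <- if (kind == "insertion") strategy$insertion_minutes$base
               else strategy$replacement_minutes$base
  }
  if (is.null(stent_cost)) stent_cost <- strategy$stent_unit_cost$base
  theatre <- minutes * (costs[["theatre_per_minute"]] +
                        costs[["surgeon_per_minute"]])
  daycase_recovery <- 30 * costs[["nurse_band6_per_minute"]] +
    (240 / 4) * costs[["nurse_band5_per_minute"]] +
    4 * costs[["bed_stay_per_hour"]]
  recovery <- daycase_fraction * daycase_recovery +
    (1 - daycase_fraction) * costs[["overnight_stay"]]
  total <- theatre + costs[["consumables_per_procedure"]] + stent_cost +
    recovery + costs[["imaging_per_procedure"]]
  if (kind == "unplanned_exchange") {
    total <- total + costs[["oncology_outpatient_visit"]]
  }
  total
}

#' Accrue discounted costs, QALYs and life years from a cohort trace
#'
#' State values (utility-weighted occupancy and alive time) are accrued
#' per cycle with discounting and, when enabled, trapezoidal half-cycle
#' correction (the average of start- and end-of-cycle occupancy values
#' each interval, equivalently weights 1/2, 1, ..., 1, 1/2 on the trace
#' rows).  Event costs are instantaneous and are not half-cycle
#' corrected: an exchange prompted at cycle `t` is performed and costed
#' at the start of the following month (discounted at cycle `t`,
#' included in a reporting horizon `m` iff `t <= m - 1`, matching
#' [stents_used()]); an infection episode at cycle `t` is costed (GP
#' visit plus an antibiotic course) at cycle `t` and included iff
#' `t <= m`.
#'
#' @param trace A `cua_trace` from [run_cohort()].
#' @param inputs The [cua_inputs()] bundle the trace came from.
#' @param utilities Optional named numeric overrides
#'   (`u_patent`, `u_uti`, `u_failed`, annual scale).
#' @param costs Optional named numeric vector of unit-cost overrides.
#' @param daycase_fraction,minutes_insertion,minutes_replacement,stent_cost
#'   Optional scalar overrides used by the sensitivity machinery.
#' @return A `cua_accrual`: data frame with one row per reporting
#'   horizon and columns `horizon`, `cost`, `qalys`, `lys`,
#'   `stents_used` (discounted GBP, QALYs, life years; stents
#'   undiscounted).
#' @export
accrue <- function(trace, inputs, utilities = NULL, costs = NULL,
                   daycase_fraction = NULL, minutes_insertion = NULL,
                   minutes_replacement = NULL, stent_cost = NULL) {
  st <- inputs$strategies[[attr(trace, "strategy")]]
  settings <- inputs$settings
  horizons <- settings$reporting_horizons
  H <- max(trace$cycle)
  if (max(horizons) > H) {
    stop("trace horizon is shorter than the largest reporting horizon",
         call. = FALSE)
  }
  u <- c(u_patent = inputs$utilities$u_patent$base,
         u_uti = inputs$utilities$u_uti$base,
         u_failed = inputs$utilities$u_failed$base)
  if (!is.null(utilities)) u[names(utilities)] <- utilities
  cb <- cost_base(inputs)
  if (!is.null(costs)) cb[names(costs)] <- costs
  missing_costs <- setdiff(required_cost_keys, names(cb))
  if (length(missing_costs)) {
    stop("missing cost entries: ", paste(missing_costs, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(daycase_fraction)) {
    daycase_fraction <- settings$daycase_fraction$base
  }

  df <- discount_factor(trace$cycle, settings$discount_rate_annual)
  # monthly utility by state; Failed retains the failed-stent utility for
  # the failure month, Dead contributes nothing
  u_state <- cbind(u[["u_patent"]], u[["u_uti"]], u[["u_failed"]], 0) / 12
  occ <- as.matrix(trace[, state_names])
  q_row <- as.vector(occ %*% t(u_state)) * df      # QALY value of each row
  ly_row <- rowSums(occ[, 1:3]) * df / 12          # alive time of each row

  c_unpl <- procedure_cost(st, cb, "unplanned_exchange", daycase_fraction,
                           minutes = minutes_replacement,
                           stent_cost = stent_cost)
  c_plan <- procedure_cost(st, cb, "planned_exchange", daycase_fraction,
                           minutes = minutes_replacement,
                           stent_cost = stent_cost)
  c_ins <- procedure_cost(st, cb, "insertion", daycase_fraction,
                          minutes = minutes_insertion,
                          stent_cost = stent_cost)
  c_uti <- cb[["gp_visit"]] + cb[["antibiotic_course"]]
  exch_cost_row <- (trace$unplanned_exchanges * c_unpl +
                    trace$planned_exchanges * c_plan) * df
  uti_cost_row <- trace$uti_episodes * c_uti * df

  hcc <- settings$half_cycle_correction
  accrue_state <- function(x_row, m) {
    if (hcc) {           # trapezoid over rows 0..m, half weight at the ends
      w <- rep(1, m + 1); w[1] <- 0.5; w[m + 1] <- 0.5
      sum(x_row[trace$cycle <= m] * w)
    } else {             # start-of-cycle convention: rows 0..m-1
      sum(x_row[trace$cycle <= m - 1])
    }
  }
  out <- do.call(rbind, lapply(horizons, function(m) {
    exch_rows <- trace$cycle >= 1 & trace$cycle <= m - 1
    uti_rows <- trace$cycle >= 1 & trace$cycle <= m
    cost <- c_ins + sum(exch_cost_row[exch_rows]) + sum(uti_cost_row[uti_rows])
    data.frame(horizon = m,
               cost = cost,
               qalys = accrue_state(q_row, m),
               lys = accrue_state(ly_row, m),
               stents_used = stents_used(trace, m)$total)
  }))
  class(out) <- c("cua_accrual", "data.frame")
  out
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost Incremental cost (intervention minus comparator), GBP.
#' @param delta_qalys Incremental QALYs.
#' @return List with `label` (`"dominant"` if cheaper and more
#'   effective, `"dominated"` if dearer and less effective,
#'   `"undefined"` if the QALY difference is zero, otherwise `"icer"`)
#'   and `value` (the ratio, `NA` under a dominance or undefined label).
#' @export
icer <- function(delta_cost, delta_qalys) {
  if (delta_qalys == 0) return(list(label = "undefined", value = NA_real_))
  if (delta_cost < 0 && delta_qalys > 0) {
    return(list(label = "dominant", value = NA_real_))
  }
  if (delta_cost > 0 && delta_qalys < 0) {
    return(list(label = "dominated", value = NA_real_))
  }
  list(label = "icer", value = delta_cost / delta_qalys)
}

#' Net monetary benefit
#'
#' `wtp * delta_qalys - delta_cost`; positive values indicate the
#' intervention is cost-effective at the given willingness to pay.
#'
#' @param delta_cost Incremental cost, GBP.
#' @param delta_qalys Incremental QALYs.
#' @param wtp Willingness to pay, GBP per QALY (>= 0).
#' @return NMB in GBP.
#' @export
nmb <- function(delta_cost, delta_qalys, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * delta_qalys - delta_cost
}

#' Run both strategies and compare them
#'
#' Convenience wrapper: runs the cohort model and accrual for both
#' strategies and assembles per-strategy and incremental outcomes at
#' every reporting horizon.  Increments are intervention (first
#' strategy) minus comparator (second strategy).
#'
#' @param inputs A [cua_inputs()] bundle.
#' @param ... Passed to [accrue()] (sensitivity overrides).
#' @param clinical_overrides Optional named list (by strategy) of
#'   monthly-probability lists passed to [run_cohort()].
#' @return A `cua_outcomes`: data frame with one row per horizon and
#'   per-strategy cost/QALY/LY/stent columns plus `delta_cost`,
#'   `delta_qalys`, `icer_label`, `icer`, `nmb`.
#' @export
compare_strategies <- function(inputs, ..., clinical_overrides = NULL) {
  nms <- vapply(inputs$strategies, function(s) s$name, "")
  acc <- lapply(nms, function(nm) {
    tr <- run_cohort(inputs, nm, clinical = clinical_overrides[[nm]])
    accrue(tr, inputs, ...)
  })
  names(acc) <- nms
  a1 <- acc[[1]]; a2 <- acc[[2]]
  out <- data.frame(horizon = a1$horizon)
  for (i in 1:2) {
    nm <- nms[i]
    out[[paste0("cost_", nm)]] <- acc[[i]]$cost
    out[[paste0("qalys_", nm)]] <- acc[[i]]$qalys
    out[[paste0("lys_", nm)]] <- acc[[i]]$lys
    out[[paste0("stents_", nm)]] <- acc[[i]]$stents_used
  }
  out$delta_cost <- a1$cost - a2$cost
  out$delta_qalys <- a1$qalys - a2$qalys
  ic <- lapply(seq_len(nrow(out)),
               function(i) icer(out$delta_cost[i], out$delta_qalys[i]))
  out$icer_label <- vapply(ic, `[[`, "", "label")
  out$icer <- vapply(ic, `[[`, numeric(1), "value")
  out$nmb <- nmb(out$delta_cost, out$delta_qalys, inputs$settings$wtp)
  attr(out, "intervention") <- nms[1]
  attr(out, "comparator") <- nms[2]
  attr(out, "wtp") <- inputs$settings$wtp
  class(out) <- c("cua_outcomes", "data.frame")
  out
}

#' @export
print.cua_outcomes <- function(x, ...) {
  cat(sprintf("<cua_outcomes: %s vs %s, WTP %s/QALY>\n",
              attr(x, "intervention"), attr(x, "comparator"),
              format(attr(x, "wtp"), big.mark = ",")))
  print.data.frame(cbind(x[, "horizon", drop = FALSE],
                         round(x[, sapply(x, is.numeric) &
                                   names(x) != "horizon"], 3),
                         icer_label = x$icer_label))
  invisible(x)
}

#' Cumulative incremental cost over time
#'
#' The month-by-month cumulative discounted incremental cost
#' (intervention minus comparator), used to locate the cost-neutral
#' month at which the dearer initial device has paid for itself.
#'
#' @param inputs A [cua_inputs()] bundle.
#' @return Data frame with columns `month` and `delta_cost`.
#' @export
increment_over_time <- function(inputs) {
  months <- seq_len(inputs$settings$horizon)
  tmp <- inputs
  tmp$settings$reporting_horizons <- months
  nms <- vapply(inputs$strategies, function(s) s$name, "")
  acc <- lapply(nms, function(nm) accrue(run_cohort(tmp, nm), tmp))
  data.frame(month = months, delta_cost = acc[[1]]$cost - acc[[2]]$cost)
}
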