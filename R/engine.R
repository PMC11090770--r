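#' @title Four-state Markov engine
#' @description
#' States are Patent, Patent-with-UTI (PatentUTI), Failed and Dead.  The
#' cohort starts all-Patent; cycles are monthly.  A failed stent is
#' replaced with a stent of the same type, so Failed is a one-cycle
#' transient state whose outgoing transitions are those of a fresh stent.
#' Dead is absorbing.
#' @name engine
NULL

state_names <- c("Patent", "PatentUTI", "Failed", "Dead")

# base-case monthly probabilities for one strategy, as a plain list
clinical_base <- function(inputs, strategy) {
  blk <- inputs$clinical$by_strategy[[strategy]]
  if (is.null(blk)) stop("unknown strategy: ", strategy, call. = FALSE)
  list(p_fail = blk$p_fail$base,
       p_uti = blk$p_uti$base,
       p_death = inputs$clinical$p_death$base,
       p_uti_resolve = inputs$clinical$p_uti_resolve$base)
}

#' Build the one-cycle transition matrix
#'
#' Monthly transition probabilities are composed marginally: from an
#' alive state, the probabilities of death (`p_death`) and stent failure
#' (`p_fail`, applied in all alive states) enter the row directly, a new
#' urinary tract infection takes `p_uti` of the remaining mass, and the
#' residual stays put.  From PatentUTI the infection resolves with
#' probability `p_uti_resolve` (resolved patients return to Patent); an
#' unresolved infection remains in PatentUTI.  From Failed the
#' replacement stent is at the same fresh-stent risks as Patent.  Rows
#' are validated to be stochastic; a probability mass exceeding 1 within
#' a state is rejected.
#'
#' @param clinical List with entries `p_fail`, `p_uti`, `p_death`,
#'   `p_uti_resolve` (monthly probabilities), e.g. from a drawn PSA
#'   sample or the base case.
#' @param cycle Cycle index; accepted for interface symmetry -- the
#'   chain is time-homogeneous and scheduled exchanges are handled as
#'   event overlays by [run_cohort()].
#' @return 4x4 row-stochastic matrix over
#'   Patent, PatentUTI, Failed, Dead.
#' @export
build_transition_matrix <- function(clinical, cycle = 0L) {
  f <- clinical$p_fail; u <- clinical$p_uti
  d <- clinical$p_death; r <- clinical$p_uti_resolve
  for (p in c(f, u, d, r)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("transition probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (f + u + d > 1 + 1e-12) {
    stop(sprintf(
      "competing transition mass p_fail + p_uti + p_death = %.4f exceeds 1",
      f + u + d), call. = FALSE)
  }
  patent <- c(1 - f - u - d, u, f, d)
  # from an active UTI: death and failure as in all alive states; the
  # infection resolves (-> Patent) or persists (-> PatentUTI)
  uti <- c((1 - f - d) * r, (1 - f - d) * (1 - r), f, d)
  M <- rbind(patent, uti, patent, c(0, 0, 0, 1))
  dimnames(M) <- list(state_names, state_names)
  stopifnot(all(abs(rowSums(M) - 1) < 1e-12), all(M >= 0))
  M
}

#' Run the Markov cohort model for one strategy
#'
#' Produces the cohort trace over cycles `0..horizon` together with
#' per-cycle expected event counts.  Events attributed to cycle `t`
#' (`t >= 1`) occur on the transition into cycle `t`:
#' * `unplanned_exchanges`: expected entries into Failed (each triggers
#'   replacement with the same stent type, carried out at the start of
#'   the following month -- see [stents_used()] for the reporting
#'   consequence);
#' * `uti_episodes`: expected new infections (entries into PatentUTI);
#' * `deaths`: expected entries into Dead;
#' * `planned_exchanges`: at each completed planned-change interval
#'   (`t` a multiple of the strategy's interval), the stent of a patient
#'   still alive and patent is exchanged if it survived the whole
#'   interval unchanged: occupancy of Patent + PatentUTI at `t` times
#'   `(1 - p_fail)^interval`.
#'
#' @param inputs A [cua_inputs()] bundle.
#' @param strategy Strategy name (must match one of `inputs$strategies`).
#' @param clinical Optional override of the monthly probabilities (list
#'   with `p_fail`, `p_uti`, `p_death`, `p_uti_resolve`), used by the
#'   sensitivity machinery; defaults to the base case.
#' @return A `cua_trace`: data frame with columns `cycle`, the four
#'   state occupancies, and the four event-count columns.
#' @export
run_cohort <- function(inputs, strategy, clinical = NULL) {
  st <- inputs$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy: ", strategy, call. = FALSE)
  if (is.null(clinical)) clinical <- clinical_base(inputs, strategy)
  H <- inputs$settings$horizon
  if (H < 1) stop("horizon must be >= 1 cycle", call. = FALSE)
  M <- build_transition_matrix(clinical)
  k <- st$planned_exchange_interval
  surv_factor <- (1 - clinical$p_fail)^k

  occ <- matrix(0, nrow = H + 1, ncol = 4,
                dimnames = list(NULL, state_names))
  occ[1, ] <- c(1, 0, 0, 0)
  unplanned <- uti <- deaths <- planned <- numeric(H + 1)
  for (t in seq_len(H)) {
    v <- occ[t, ]
    occ[t + 1, ] <- v %*% M
    unplanned[t + 1] <- sum(v * M[, "Failed"])
    # new infection episodes: entries into PatentUTI from other states
    # (an unresolved infection persisting in PatentUTI is the same episode)
    uti[t + 1] <- sum(v[c(1, 3)] * M[c(1, 3), "PatentUTI"])
    deaths[t + 1] <- sum(v * M[, "Dead"]) - v[["Dead"]]
    if (t %% k == 0) {
      planned[t + 1] <- (occ[t + 1, "Patent"] + occ[t + 1, "PatentUTI"]) *
        surv_factor
    }
  }
  # events at cycle t are stored at row t + 1, aligned with the trace rows
  out <- data.frame(cycle = 0:H, occ, unplanned_exchanges = unplanned,
                    planned_exchanges = planned, uti_episodes = uti,
                    deaths = deaths, check.names = FALSE)
  attr(out, "strategy") <- strategy
  attr(out, "clinical") <- clinical
  attr(out, "interval") <- k
  class(out) <- c("cua_trace", "data.frame")
  out
}

#' Cumulative stents used at a reporting horizon
#'
#' Total stents per initial patient: the initial insertion plus all
#' exchanges performed within the horizon.  An exchange prompted by an
#' event at cycle `t` is performed at the start of month `t + 1`, so a
#' horizon of `m` months covers events at cycles `1 .. m - 1`; in
#' particular a planned change falling due exactly at the horizon (e.g.
#' the metallic stent's month-12 change in a 12-month report) lies just
#' outside it.
#'
#' @param trace A `cua_trace` from [run_cohort()].
#' @param horizon Reporting horizon in months (defaults to the full
#'   trace).
#' @return Named list with `unplanned`, `planned`, `total` expected
#'   stent counts.
#' @export
stents_used <- function(trace, horizon = max(trace$cycle)) {
  if (horizon < 1 || horizon > max(trace$cycle)) {
    stop("`horizon` must lie within the simulated trace", call. = FALSE)
  }
  rows <- trace$cycle >= 1 & trace$cycle <= horizon - 1
  un <- sum(trace$unplanned_exchanges[rows])
  pl <- sum(trace$planned_exchanges[rows])
  list(unplanned = un, planned = pl, total = 1 + un + pl)
}

#' Patient-level microsimulation oracle
#'
#' Simulates `n` independent patients with per-cycle categorical draws
#' under exactly the rules of [run_cohort()] (including the
#' survivor-factor planned-exchange rule, drawn per patient as a
#' Bernoulli event).  Serves as an independent stochastic check on the
#' deterministic cohort engine: occupancies and event tallies converge
#' to the cohort values at rate `1/sqrt(n)`.
#'
#' @inheritParams run_cohort
#' @param n Number of simulated patients.
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return List with `occupancy` (mean per cycle), `occupancy_se`,
#'   `stents` (data frame of total stents used at each reporting
#'   horizon, with Monte-Carlo standard errors), `events` (mean
#'   cumulative UTI episodes and deaths at the full horizon with SEs),
#'   `economics` (mean discounted cost and QALYs per patient at the
#'   full horizon, with SEs, under the same costing and accrual
#'   conventions as [accrue()]) and `n`.
#' @export
microsim_oracle <- function(inputs, strategy, n, seed, clinical = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  st <- inputs$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy: ", strategy, call. = FALSE)
  if (is.null(clinical)) clinical <- clinical_base(inputs, strategy)
  H <- inputs$settings$horizon
  M <- build_transition_matrix(clinical)
  cumM <- t(apply(M, 1, cumsum))
  k <- st$planned_exchange_interval
  surv_factor <- (1 - clinical$p_fail)^k
  horizons <- inputs$settings$reporting_horizons

  # unit values for per-patient discounted economics, matching accrue()
  cb <- cost_base(inputs)
  dc <- inputs$settings$daycase_fraction$base
  c_ins <- procedure_cost(st, cb, "insertion", dc)
  c_unpl <- procedure_cost(st, cb, "unplanned_exchange", dc)
  c_plan <- procedure_cost(st, cb, "planned_exchange", dc)
  c_uti <- cb[["gp_visit"]] + cb[["antibiotic_course"]]
  u_month <- c(inputs$utilities$u_patent$base, inputs$utilities$u_uti$base,
               inputs$utilities$u_failed$base, 0) / 12
  df <- discount_factor(0:H, inputs$settings$discount_rate_annual)
  hcc <- inputs$settings$half_cycle_correction

  set.seed(seed)
  state <- rep(1L, n)
  occ_sum <- matrix(0, H + 1, 4, dimnames = list(NULL, state_names))
  occ_sum[1, 1] <- n
  un_count <- integer(n)   # per-patient unplanned exchanges performed
  pl_count <- integer(n)
  uti_count <- integer(n)
  cost_acc <- rep(c_ins, n)
  qaly_acc <- (if (hcc) 0.5 else 1) * u_month[1L] * df[1]  # all start Patent
  qaly_acc <- rep(qaly_acc, n)
  snapshots <- vector("list", length(horizons))
  names(snapshots) <- as.character(horizons)

  for (t in seq_len(H)) {
    r <- stats::runif(n)
    alive <- state != 4L
    new_state <- state
    for (s in 1:3) {
      idx <- which(state == s)
      if (length(idx)) {
        new_state[idx] <- findInterval(r[idx], cumM[s, ], left.open = TRUE) + 1L
      }
    }
    fail_now <- alive & new_state == 3L
    uti_now <- alive & state != 2L & new_state == 2L
    un_count <- un_count + as.integer(fail_now)
    uti_count <- uti_count + as.integer(uti_now)
    cost_acc <- cost_acc + c_uti * df[t + 1] * uti_now
    if (t <= H - 1) cost_acc <- cost_acc + c_unpl * df[t + 1] * fail_now
    state <- new_state
    if (t %% k == 0) {
      elig <- state %in% c(1L, 2L)
      planned_now <- elig & stats::runif(n) < surv_factor
      pl_count <- pl_count + as.integer(planned_now)
      if (t <= H - 1) cost_acc <- cost_acc + c_plan * df[t + 1] * planned_now
    }
    w <- if (!hcc && t == H) 0 else if (hcc && t == H) 0.5 else 1
    qaly_acc <- qaly_acc + w * u_month[state] * df[t + 1]
    occ_sum[t + 1, ] <- tabulate(state, nbins = 4)
    # events at cycle t are performed at t + 1, hence counted at m if t <= m - 1
    m <- match(as.character(t + 1), names(snapshots))
    if (!is.na(m)) snapshots[[m]] <- 1L + un_count + pl_count
  }
  for (m in seq_along(snapshots)) {   # horizons beyond H - 1 (none normally)
    if (is.null(snapshots[[m]])) snapshots[[m]] <- 1L + un_count + pl_count
  }

  occupancy <- occ_sum / n
  occupancy_se <- sqrt(pmax(occupancy * (1 - occupancy), 0) / n)
  stents <- do.call(rbind, lapply(seq_along(horizons), function(i) {
    x <- snapshots[[i]]
    data.frame(horizon = horizons[i], total = mean(x),
               se = stats::sd(x) / sqrt(n))
  }))
  events <- data.frame(
    quantity = c("uti_episodes", "deaths"),
    mean = c(mean(uti_count), mean(state == 4L)),
    se = c(stats::sd(uti_count) / sqrt(n),
           stats::sd(state == 4L) / sqrt(n)))
  economics <- data.frame(
    quantity = c("cost", "qalys"),
    mean = c(mean(cost_acc), mean(qaly_acc)),
    se = c(stats::sd(cost_acc) / sqrt(n), stats::sd(qaly_acc) / sqrt(n)))
  list(occupancy = occupancy, occupancy_se = occupancy_se,
       stents = stents, events = events, economics = economics, n = n)
}
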