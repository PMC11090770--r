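#' The published base-case input bundle
#'
#' Clinical transition probabilities, planned-exchange intervals and
#' procedure times carry their published base-case values and bounds
#' (`provenance = "published"`).  Unit costs and utilities are held in
#' source appendices that are not machine-readable; they ship here as
#' round-number placeholders (`provenance = "placeholder"`) with
#' realistic UK magnitudes (PSSRU-style staff rates, NHS-tariff-style
#' visit costs) so the full pipeline runs standalone.  Every placeholder
#' is overridable from a configuration file; economic outputs computed
#' from placeholders must not be quoted as the published results.
#'
#' @return A validated [cua_inputs()] bundle.
#' @export
base_case_fixture <- function() {
  pub <- function(base, low, high, family = "beta") {
    param_value(base, low, high, family = family, provenance = "published")
  }
  ph <- function(base, low = base * 0.8, high = base * 1.2,
                 family = "gamma") {
    param_value(base, low, high, family = family, provenance = "placeholder")
  }
  strategies <- list(
    Resonance = stent_strategy(
      name = "Resonance", planned_exchange_interval = 12,
      stent_unit_cost = param_value(750, 600, 900, family = "gamma",
                                    provenance = "placeholder"),
      insertion_minutes = param_value(21, 21 * 0.8, 21 * 1.2,
                                      family = "gamma",
                                      provenance = "published"),
      replacement_minutes = param_value(31, 31 * 0.8, 31 * 1.2,
                                        family = "gamma",
                                        provenance = "published")),
    JJ = stent_strategy(
      name = "JJ", planned_exchange_interval = 6,
      stent_unit_cost = param_value(30, 30, 60, family = "gamma",
                                    provenance = "placeholder"),
      insertion_minutes = param_value(20.6, 20.6 * 0.8, 20.6 * 1.2,
                                      family = "gamma",
                                      provenance = "published"),
      replacement_minutes = param_value(30.6, 30.6 * 0.8, 30.6 * 1.2,
                                        family = "gamma",
                                        provenance = "published")))
  clinical <- list(
    p_death = pub(0.0505, 0.0404, 0.0606),
    # infections clear within one monthly cycle; the base resolution
    # probability is set so its +10% sensitivity bound is exactly 1
    p_uti_resolve = param_value(1 / 1.1, 1 / 1.1 * 0.9, 1, family = "beta",
                                provenance = "modelling assumption"),
    by_strategy = list(
      Resonance = list(p_fail = pub(0.1502, 0.1202, 0.1802),
                       p_uti = pub(0.0205, 0.0018, 0.0547)),
      JJ = list(p_fail = pub(0.3648, 0.2918, 0.4378),
                p_uti = pub(0.0085, 0.0068, 0.0102))))
  utilities <- list(
    u_patent = param_value(0.80, 0.64, 0.96, family = "beta",
                           provenance = "placeholder"),
    u_uti = param_value(0.70, 0.56, 0.84, family = "beta",
                        provenance = "placeholder"),
    u_failed = param_value(0.75, 0.60, 0.90, family = "beta",
                           provenance = "placeholder"))
  costs <- list(
    theatre_per_minute = ph(20),
    surgeon_per_minute = ph(2),
    nurse_band6_per_minute = ph(1),
    nurse_band5_per_minute = ph(0.75),
    consumables_per_procedure = ph(100),
    bed_stay_per_hour = ph(20),
    overnight_stay = ph(400),
    imaging_per_procedure = ph(50),
    gp_visit = ph(40),
    antibiotic_course = ph(10),
    oncology_outpatient_visit = ph(200))
  cua_inputs(model_settings(), strategies, clinical, utilities, costs)
}

#' Synthetic UK-style life table (placeholder values)
#'
#' Round-number annual death probabilities by sex for ages 57-62,
#' shaped like national life tables (male mortality above female,
#' increasing with age).  Synthetic: used to exercise
#' [blend_mortality()] and to calibrate the fixture's study-mortality
#' component so the blended monthly probability equals the base-case
#' 0.0505.
#'
#' @return Data frame with columns `age`, `male`, `female`.
#' @export
synthetic_life_table <- function() {
  data.frame(age = 57:62,
             male = c(0.0080, 0.0088, 0.0096, 0.0105, 0.0115, 0.0126),
             female = c(0.0052, 0.0057, 0.0062, 0.0068, 0.0074, 0.0081))
}

#' Study-mortality component calibrated to the blended base case
#'
#' Returns the monthly study-derived death probability which, blended
#' with [synthetic_life_table()] mortality (33% male, ages 57-62) via
#' [blend_mortality()], reproduces the base-case all-cause monthly
#' probability exactly.
#'
#' @param target Blended monthly probability to calibrate to.
#' @return Monthly study death probability.
#' @export
calibrated_study_mortality <- function(target = 0.0505) {
  lt <- synthetic_life_table()
  w <- c(male = 0.33, female = 0.67)
  q_annual <- mean(as.matrix(lt[, names(w)]) %*% w)
  h_bg <- probability_to_rate(q_annual, t = 12)
  h_total <- probability_to_rate(target, t = 1)
  if (h_total <= h_bg) {
    stop("background mortality alone exceeds the blend target", call. = FALSE)
  }
  rate_to_probability(h_total - h_bg, t = 1)
}

#' Synthesize a digitised Kaplan-Meier survival series
#'
#' Generates monthly stent-survival coordinates under a known constant
#' monthly failure probability, `S(t) = (1 - p)^t`, with multiplicative
#' log-normal digitisation noise -- a stand-in for coordinates read off
#' a published curve, used to exercise [km_constant_hazard()] parameter
#' recovery.
#'
#' @param monthly_failure_probability True monthly failure probability,
#'   in `(0, 1)`.
#' @param horizon Number of monthly points (>= 2).
#' @param noise_sd Standard deviation of the log-scale noise (0 gives
#'   the exact geometric series).
#' @param seed Integer seed.
#' @return Data frame with columns `time` (months) and `survival`,
#'   clamped to `(0, 1]` and made non-increasing so the series remains
#'   a valid survival curve.
#' @export
synthesize_km_series <- function(monthly_failure_probability, horizon,
                                 noise_sd = 0, seed = 1) {
  p <- monthly_failure_probability
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("`monthly_failure_probability` must lie in (0, 1)", call. = FALSE)
  }
  if (horizon < 2) stop("`horizon` must be >= 2 months", call. = FALSE)
  set.seed(seed)
  t <- seq_len(horizon)
  s <- (1 - p)^t
  if (noise_sd > 0) {
    s <- s * exp(stats::rnorm(horizon, 0, noise_sd))
    s <- pmin(s, 1)
    s <- cummin(s)  # keep the digitised curve a valid survival function
    s <- pmax(s, 1e-12)
  }
  data.frame(time = t, survival = s)
}

#' Synthesize a plausible cost/utility parameter block
#'
#' Draws positive unit costs (gamma-distributed around the fixture's
#' placeholder magnitudes) and state utilities in `(0, 1)` ordered
#' `u_patent >= u_uti >= u_failed`, mirroring the structure of the
#' appendix-held economic inputs so the economics and sensitivity
#' stages can be tested on many randomised but schema-valid input sets.
#'
#' @param seed Integer seed; same seed, same block.
#' @return Named list with `utilities` and `costs` blocks of
#'   [param_value()]s, directly usable in [cua_inputs()].
#' @export
synthesize_economic_inputs <- function(seed = 1) {
  set.seed(seed)
  base <- base_case_fixture()
  costs <- lapply(base$costs, function(pv) {
    draw <- stats::rgamma(1, shape = 25, scale = pv$base / 25)
    param_value(draw, draw * 0.8, draw * 1.2, family = "gamma",
                provenance = "synthetic")
  })
  # ordering constraint: patent >= uti >= failed
  u <- sort(stats::rbeta(3, 8, 2), decreasing = TRUE)
  utilities <- list(
    u_patent = param_value(u[1], max(u[1] - 0.1, 0), min(u[1] + 0.1, 1),
                           family = "beta", provenance = "synthetic"),
    u_uti = param_value(u[2], max(u[2] - 0.1, 0), min(u[2] + 0.1, 1),
                        family = "beta", provenance = "synthetic"),
    u_failed = param_value(u[3], max(u[3] - 0.1, 0), min(u[3] + 0.1, 1),
                           family = "beta", provenance = "synthetic"))
  list(utilities = utilities, costs = costs)
}
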