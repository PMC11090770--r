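#' Convert a constant hazard rate to a transition probability
#'
#' Under a constant (exponential) hazard, the probability that at least one
#' event occurs in a window of length `t` is `1 - exp(-rate * t)`.  All
#' clinical transition probabilities in the model are derived on this
#' constant-monthly-hazard assumption.
#'
#' @param rate Event rate, in events per unit time. Must be non-negative.
#' @param t Duration, in the same time unit as `rate`. Must be positive.
#' @return Probability of at least one event in `(0, t]`.
#' @seealso [probability_to_rate()] for the inverse transformation.
#' @examples
#' rate_to_probability(0.4539, 1)  # ~0.3648, monthly failure from rate
#' @export
rate_to_probability <- function(rate, t = 1) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be a finite, non-negative event rate", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be a finite, positive duration", call. = FALSE)
  }
  1 - exp(-rate * t)
}

#' Convert a transition probability back to a constant hazard rate
#'
#' Inverse of [rate_to_probability()]: `-log(1 - p) / t`.
#'
#' @param p Probability in `[0, 1)`.
#' @param t Duration over which `p` applies. Must be positive.
#' @return Constant event rate per unit time.
#' @export
probability_to_rate <- function(p, t = 1) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must be a probability in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be a finite, positive duration", call. = FALSE)
  }
  -log(1 - p) / t
}

#' Monthly probability from pooled event counts and person-time
#'
#' Converts a pooled incidence (events over total patient-months of
#' follow-up) into a monthly transition probability via the constant-hazard
#' assumption.  This is how the base-case urinary-tract-infection
#' probability is obtained from multiple published cohorts.
#'
#' @param events Total event count across pooled studies (>= 0).
#' @param exposure Total follow-up in patient-months (> 0).
#' @return Monthly probability of the event.
#' @export
pooled_incidence_probability <- function(events, exposure) {
  if (!is.finite(events) || events < 0) {
    stop("`events` must be a non-negative count", call. = FALSE)
  }
  if (!is.finite(exposure) || exposure <= 0) {
    stop("`exposure` must be positive patient-time", call. = FALSE)
  }
  rate_to_probability(events / exposure, t = 1)
}

#' Fit a constant monthly hazard to a digitised Kaplan-Meier series
#'
#' Takes coordinates read off a published Kaplan-Meier curve -- pairs of
#' (time in months, surviving proportion) -- and fits a single constant
#' hazard by least squares on the log-survival scale through the origin:
#' `lambda = -sum(t * log(S)) / sum(t^2)`.  Under the exponential model
#' `log S(t) = -lambda * t`, this is the ordinary least-squares slope.
#'
#' @param times Event-scale times, strictly increasing, in months.
#' @param survival Surviving proportions in `(0, 1]`, non-increasing.
#' @return Implied monthly failure probability `1 - exp(-lambda)`.
#' @examples
#' # exact geometric series is recovered exactly
#' km_constant_hazard(1:12, 0.85^(1:12))  # 0.15
#' @export
km_constant_hazard <- function(times, survival) {
  if (length(times) < 1 || length(times) != length(survival)) {
    stop("need at least one (time, survival) pair of equal length",
         call. = FALSE)
  }
  if (any(diff(times) <= 0) || any(times <= 0)) {
    stop("`times` must be positive and strictly increasing", call. = FALSE)
  }
  if (any(survival > 1) || any(survival <= 0)) {
    stop("`survival` must lie in (0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 0)) {
    stop("`survival` must be non-increasing", call. = FALSE)
  }
  lambda <- -sum(times * log(survival)) / sum(times^2)
  rate_to_probability(lambda, t = 1)
}

#' Blend study mortality with general-population life-table mortality
#'
#' Combines a study-derived monthly death probability with background
#' all-cause mortality from sex-specific annual life tables, weighted by
#' the cohort's sex mix and averaged over the cohort's age range.  The two
#' sources are combined additively on the hazard scale (independent
#' competing sources of death), then converted back to a monthly
#' probability.
#'
#' @param study_monthly_probability Monthly death probability pooled from
#'   the clinical studies.
#' @param life_table Data frame with columns `age` and one annual
#'   probability column per sex (e.g. `male`, `female`), probabilities of
#'   death within the year at each age.
#' @param sex_weights Named numeric vector of cohort sex proportions whose
#'   names match the life-table columns; must sum to 1.
#' @param age_range Integer vector of ages to average over (e.g. `57:62`).
#' @return Combined monthly all-cause death probability.
#' @export
blend_mortality <- function(study_monthly_probability, life_table,
                            sex_weights, age_range) {
  if (!is.finite(study_monthly_probability) ||
      study_monthly_probability < 0 || study_monthly_probability >= 1) {
    stop("`study_monthly_probability` must lie in [0, 1)", call. = FALSE)
  }
  if (abs(sum(sex_weights) - 1) > 1e-8) {
    stop("`sex_weights` must sum to 1", call. = FALSE)
  }
  missing_cols <- setdiff(names(sex_weights), names(life_table))
  if (length(missing_cols)) {
    stop("life table lacks sex column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  slice <- life_table[life_table$age %in% age_range, , drop = FALSE]
  if (nrow(slice) == 0) {
    stop("life table has no rows for the requested age range", call. = FALSE)
  }
  q_cols <- as.matrix(slice[, names(sex_weights), drop = FALSE])
  if (any(q_cols < 0) || any(q_cols > 1)) {
    stop("life-table probabilities must lie in [0, 1]", call. = FALSE)
  }
  # sex-weighted annual probability, averaged over the age range
  q_annual <- mean(q_cols %*% sex_weights)
  h_background <- probability_to_rate(q_annual, t = 12)  # monthly hazard
  h_study <- probability_to_rate(study_monthly_probability, t = 1)
  rate_to_probability(h_study + h_background, t = 1)
}
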