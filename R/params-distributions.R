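#' Moment-matched beta distribution for a bounded parameter
#'
#' Probabilities and utilities are varied in probabilistic sensitivity
#' analysis with beta distributions, fitted by the method of moments:
#' `nu = mean (1 - mean) / sd^2 - 1`, `alpha = mean nu`,
#' `beta = (1 - mean) nu`.
#'
#' @param mean Target mean, strictly inside `(0, 1)`.
#' @param sd Target standard deviation; must satisfy
#'   `sd^2 < mean (1 - mean)`.
#' @return A `dist_spec` with `family = "beta"` and fitted shapes.
#' @export
fit_beta <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta `mean` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.finite(sd) || sd <= 0) {
    stop("`sd` must be positive; use a degenerate spec for sd = 0",
         call. = FALSE)
  }
  if (sd^2 >= mean * (1 - mean)) {
    stop(sprintf(
      "beta sd too large for the mean: need sd^2 < mean*(1-mean) = %.6g",
      mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  dist_spec("beta", mean = mean, sd = sd,
            shape = c(alpha = mean * nu, beta = (1 - mean) * nu))
}

#' Moment-matched gamma distribution for a non-negative parameter
#'
#' Costs and resource-use quantities are varied with gamma distributions
#' (right-skewed, non-negative): shape `k = mean^2 / sd^2`, scale
#' `theta = sd^2 / mean`, so that `k * theta = mean` exactly.
#'
#' @param mean Target mean (> 0).
#' @param sd Target standard deviation (> 0).
#' @return A `dist_spec` with `family = "gamma"` and fitted shape/scale.
#' @export
fit_gamma <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) {
    stop("gamma `mean` must be positive", call. = FALSE)
  }
  if (!is.finite(sd) || sd <= 0) {
    stop("`sd` must be positive; use a degenerate spec for sd = 0",
         call. = FALSE)
  }
  dist_spec("gamma", mean = mean, sd = sd,
            shape = c(shape = mean^2 / sd^2, scale = sd^2 / mean))
}

#' Construct a distribution specification
#'
#' Container for a fitted sampling distribution used in probabilistic
#' sensitivity analysis.  `family = "degenerate"` denotes a point mass at
#' `mean` (used when a parameter carries no uncertainty).
#'
#' @param family One of `"beta"`, `"gamma"`, `"degenerate"`.
#' @param mean Distribution mean.
#' @param sd Distribution standard deviation (0 for degenerate).
#' @param shape Named numeric vector of fitted shape parameters.
#' @return Object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "degenerate"),
                      mean, sd = 0, shape = numeric()) {
  family <- match.arg(family)
  structure(list(family = family, mean = mean, sd = sd, shape = shape),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s: mean %.6g, sd %.6g>\n", x$family, x$mean, x$sd))
  invisible(x)
}

#' Mean of a fitted distribution specification
#'
#' @param spec A `dist_spec`.
#' @return Analytic mean implied by the fitted shape parameters.
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
    beta = spec$shape[["alpha"]] / (spec$shape[["alpha"]] + spec$shape[["beta"]]),
    gamma = spec$shape[["shape"]] * spec$shape[["scale"]],
    degenerate = spec$mean)
}

#' Standard deviation of a fitted distribution specification
#'
#' @param spec A `dist_spec`.
#' @return Analytic standard deviation implied by the fitted shapes.
#' @export
dist_sd <- function(spec) {
  switch(spec$family,
    beta = {
      a <- spec$shape[["alpha"]]; b <- spec$shape[["beta"]]
      sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    },
    gamma = sqrt(spec$shape[["shape"]]) * spec$shape[["scale"]],
    degenerate = 0)
}

#' Draw random samples from a distribution specification
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1) {
  switch(spec$family,
    beta = stats::rbeta(n, spec$shape[["alpha"]], spec$shape[["beta"]]),
    gamma = stats::rgamma(n, shape = spec$shape[["shape"]],
                          scale = spec$shape[["scale"]]),
    degenerate = rep(spec$mean, n))
}

#' Fit the PSA sampling distribution for one uncertain parameter
#'
#' Interprets a parameter's (low, high) bounds as a central 95% interval,
#' `sd = (high - low) / 3.92` (the default, standard practice when only
#' plausible bounds are published), or as `sd = (high - low) / 2` under
#' `spread = "range2"`.  A parameter with `low == high` yields a
#' degenerate point mass.
#'
#' @param pv A [param_value()].
#' @param spread `"ci95"` (default) or `"range2"`.
#' @return A `dist_spec`.
#' @export
fit_param_dist <- function(pv, spread = c("ci95", "range2")) {
  spread <- match.arg(spread)
  stopifnot(inherits(pv, "param_value"))
  sd <- switch(spread,
               ci95 = (pv$high - pv$low) / 3.92,
               range2 = (pv$high - pv$low) / 2)
  if (sd == 0) return(dist_spec("degenerate", mean = pv$base))
  switch(pv$family,
         beta = fit_beta(pv$base, sd),
         gamma = fit_gamma(pv$base, sd),
         stop("unknown distribution family: ", pv$family, call. = FALSE))
}
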