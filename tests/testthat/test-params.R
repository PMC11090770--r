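test_that("rate/probability conversion matches the closed form and inverts", {
  expect_identical(rate_to_probability(0, 1), 0)
  expect_lt(abs(rate_to_probability(0.4539, 1) - 0.3648), 1e-4)
  expect_equal(rate_to_probability(1, 1), 1 - exp(-1))

  # round trip over a grid of rates and durations (restricted to the
  # range where 1 - p is representable in double precision)
  for (t in c(1 / 12, 1, 6, 12)) {
    r <- seq(0, min(10, 20 / t), length.out = 25)
    expect_equal(probability_to_rate(rate_to_probability(r, t), t), r,
                 tolerance = 1e-9)
  }

  expect_error(rate_to_probability(-0.1, 1), "non-negative")
  expect_error(rate_to_probability(0.1, 0), "positive")
  expect_error(probability_to_rate(1, 1), "\\[0, 1\\)")
})

test_that("pooled incidence converts events per patient-month correctly", {
  expect_identical(pooled_incidence_probability(0, 100), 0)
  expect_equal(pooled_incidence_probability(1, 1), 0.6321, tolerance = 1e-4)
  # any events/exposure ratio of 0.02071 gives the base-case UTI value
  expect_lt(abs(pooled_incidence_probability(20.71, 1000) - 0.0205), 5e-6)
  expect_error(pooled_incidence_probability(1, 0), "positive")
})

test_that("km_constant_hazard recovers exact series and rejects bad input", {
  # exact geometric survival: recovery to within 1e-10
  expect_equal(km_constant_hazard(1:12, 0.85^(1:12)), 0.15, tolerance = 1e-10)
  # exact exponential: closed form 1 - exp(-0.1)
  expect_equal(km_constant_hazard(1:24, exp(-0.1 * (1:24))), 1 - exp(-0.1),
               tolerance = 1e-12)
  # single point is enough for a through-the-origin fit
  expect_equal(km_constant_hazard(6, 0.5), 1 - 0.5^(1 / 6), tolerance = 1e-12)

  expect_error(km_constant_hazard(numeric(), numeric()), "at least one")
  expect_error(km_constant_hazard(c(1, 2), c(0.9, 1.1)), "\\(0, 1\\]")
  expect_error(km_constant_hazard(c(2, 1), c(0.9, 0.8)), "increasing")
  expect_error(km_constant_hazard(c(1, 2), c(0.8, 0.9)), "non-increasing")
})

test_that("km fit recovers the generating hazard from noisy digitised series", {
  for (p_true in c(0.1502, 0.3648)) {
    s <- synthesize_km_series(p_true, horizon = 24, noise_sd = 0.05, seed = 7)
    p_hat <- km_constant_hazard(s$time, s$survival)
    expect_lt(abs(p_hat - p_true), 0.02)
  }
})

test_that("mortality blending composes hazards additively", {
  lt0 <- data.frame(age = 57:62, male = 0, female = 0)
  w <- c(male = 0.33, female = 0.67)
  # no background mortality: study probability passes through
  expect_equal(blend_mortality(0.05, lt0, w, 57:62), 0.05)

  # equal sex weights, identical annual q: monthly component 1-(1-q)^(1/12)
  q <- 0.012
  lt <- data.frame(age = 57:62, male = q, female = q)
  expect_equal(blend_mortality(0, lt, c(male = 0.5, female = 0.5), 57:62),
               1 - (1 - q)^(1 / 12), tolerance = 1e-12)

  # fixture calibration: study component + synthetic life table = 0.0505
  p_study <- calibrated_study_mortality(0.0505)
  expect_equal(
    blend_mortality(p_study, synthetic_life_table(), w, 57:62),
    0.0505, tolerance = 1e-12)

  expect_error(blend_mortality(0.05, lt, w, 90:95), "no rows")
  expect_error(blend_mortality(0.05, lt, c(male = 0.6, female = 0.6), 57:62),
               "sum to 1")
})

test_that("beta moment matching reproduces mean and sd exactly", {
  # symmetry at mean 1/2
  s <- fit_beta(0.5, 0.1)
  expect_equal(unname(s$shape["alpha"]), unname(s$shape["beta"]))

  cases <- list(c(0.1502, (0.1802 - 0.1202) / 3.92),
                c(0.5, 0.1), c(0.0505, 0.005), c(0.9091, 0.04))
  for (cs in cases) {
    s <- fit_beta(cs[1], cs[2])
    expect_equal(dist_mean(s), cs[1], tolerance = 1e-10)
    expect_equal(dist_sd(s), cs[2], tolerance = 1e-10)
  }
  expect_error(fit_beta(0.5, 0.6), "sd\\^2 < mean")
  expect_error(fit_beta(1.2, 0.1), "\\(0, 1\\)")
})

test_that("gamma moment matching reproduces mean and sd exactly", {
  s <- fit_gamma(100, 10)
  expect_equal(unname(s$shape["shape"]), 100)
  expect_equal(unname(s$shape["scale"]), 1)
  for (cs in list(c(100, 10), c(750, 76.5), c(0.75, 0.2))) {
    s <- fit_gamma(cs[1], cs[2])
    expect_equal(dist_mean(s), cs[1], tolerance = 1e-10)
    expect_equal(dist_sd(s), cs[2], tolerance = 1e-10)
  }
  expect_error(fit_gamma(-1, 1), "positive")
})

test_that("sampling from fitted distributions reproduces the mean", {
  set.seed(11)
  n <- 1e6
  for (s in list(fit_beta(0.1502, 0.0153), fit_gamma(750, 76.5))) {
    draws <- sample_dist(s, n)
    expect_lt(abs(mean(draws) - s$mean), 3 * s$sd / sqrt(n))
  }
})

test_that("fit_param_dist honours spread conventions and degeneracy", {
  pv <- param_value(0.1502, 0.1202, 0.1802, family = "beta")
  expect_equal(fit_param_dist(pv)$sd, (0.1802 - 0.1202) / 3.92)
  expect_equal(fit_param_dist(pv, "range2")$sd, (0.1802 - 0.1202) / 2)
  fixed <- param_value(0.5, family = "beta")
  expect_identical(fit_param_dist(fixed)$family, "degenerate")
  expect_identical(sample_dist(fit_param_dist(fixed), 3), rep(0.5, 3))
})

test_that("param_value enforces ordering and family bounds", {
  expect_error(param_value(0.5, 0.6, 0.7, family = "beta"), "low <= base")
  expect_error(param_value(0.5, 0.1, 1.2, family = "beta"), "\\[0, 1\\]")
  expect_error(param_value(-5, -6, -4, family = "gamma"), "non-negative")
})

test_that("input documents round-trip through YAML and JSON with validation", {
  inp <- base_case_fixture()
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("inputs.", ext))
    write_inputs(inp, path)
    back <- read_inputs(path)
    expect_equal(back, inp, tolerance = 1e-12)
    # a second write is byte-identical (stable serialisation)
    path2 <- file.path(tempdir(), paste0("inputs2.", ext))
    write_inputs(back, path2)
    expect_identical(readBin(path, "raw", file.size(path)),
                     readBin(path2, "raw", file.size(path2)))
  }
})

test_that("schema violations are reported with their dotted path", {
  path <- file.path(tempdir(), "broken.yaml")
  write_inputs(base_case_fixture(), path)
  doc <- yaml::read_yaml(path)
  doc$clinical$by_strategy$JJ$p_fail$base <- 1.4
  yaml::write_yaml(doc, path)
  expect_error(read_inputs(path), "JJ.p_fail")

  doc$clinical$by_strategy$JJ$p_fail <- NULL
  yaml::write_yaml(doc, path)
  expect_error(read_inputs(path), "p_fail")

  doc$costs <- NULL
  yaml::write_yaml(doc, path)
  expect_error(read_inputs(path), "costs")
})

test_that("validate_inputs rejects excessive competing transition mass", {
  inp <- base_case_fixture()
  inp$clinical$by_strategy$JJ$p_fail <-
    param_value(0.95, 0.9, 1, family = "beta")
  expect_error(validate_inputs(inp), "exceeds 1")
})
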