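test_that("discount factors follow the continuous-per-cycle convention", {
  expect_identical(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035)
  expect_equal(discount_factor(60, 0.035), 1.035^-5)
  expect_equal(discount_factor(6, 0), 1)
  expect_error(discount_factor(-1, 0.035), ">= 0")
})

test_that("procedure costs are built bottom-up and respond linearly", {
  st <- fixture$strategies$Resonance
  zero <- setNames(rep(0, length(fixture$costs)), names(fixture$costs))
  expect_equal(procedure_cost(st, zero, "insertion", stent_cost = 0), 0)

  # replacement takes 10 minutes longer than insertion for both stents
  expect_equal(fixture$strategies$Resonance$replacement_minutes$base, 31)
  expect_equal(fixture$strategies$JJ$replacement_minutes$base, 30.6)

  cb <- cost_base <- vapply(fixture$costs, function(p) p$base, numeric(1))
  c1 <- procedure_cost(st, cb, "insertion")
  c2 <- procedure_cost(st, cb, "insertion",
                       stent_cost = 2 * st$stent_unit_cost$base)
  expect_equal(c2 - c1, st$stent_unit_cost$base)

  # unplanned exchanges add the unplanned oncology outpatient visit
  expect_equal(
    procedure_cost(st, cb, "unplanned_exchange") -
      procedure_cost(st, cb, "planned_exchange"),
    cb[["oncology_outpatient_visit"]])

  # a lower day-case share substitutes overnight-stay cost for recovery
  dc1 <- procedure_cost(st, cb, "insertion", daycase_fraction = 1)
  dc75 <- procedure_cost(st, cb, "insertion", daycase_fraction = 0.75)
  daycase_recovery <- 30 * cb[["nurse_band6_per_minute"]] +
    60 * cb[["nurse_band5_per_minute"]] + 4 * cb[["bed_stay_per_hour"]]
  expect_equal(dc75 - dc1, 0.25 * (cb[["overnight_stay"]] - daycase_recovery))

  expect_error(procedure_cost(st, cb, "refurbishment"), "arg")
})

test_that("an immortal patent cohort accrues exactly utility x years", {
  inp <- inert_inputs(u_patent_annual = 1)
  inp$settings$discount_rate_annual <- 0
  zero_costs <- lapply(fixture$costs, function(p) param_value(0))
  names(zero_costs) <- names(fixture$costs)
  inp$costs <- zero_costs
  for (i in seq_along(inp$strategies)) {
    inp$strategies[[i]]$stent_unit_cost <- param_value(0)
  }
  tr <- run_cohort(inp, "Resonance")
  acc <- accrue(tr, inp)
  expect_equal(acc$qalys[acc$horizon == 60], 5)
  expect_equal(acc$lys[acc$horizon == 60], 5)
  expect_equal(acc$cost[acc$horizon == 60], 0)

  # zero utilities give zero QALYs regardless of the trace
  acc0 <- accrue(run_cohort(fixture, "JJ"), fixture,
                 utilities = c(u_patent = 0, u_uti = 0, u_failed = 0))
  expect_equal(acc0$qalys, rep(0, 4))
})

test_that("half-cycle corrected accrual lies between cycle-start and cycle-end sums", {
  tr <- run_cohort(fixture, "JJ")
  inp_hcc <- fixture
  inp_nohcc <- fixture
  inp_nohcc$settings$half_cycle_correction <- FALSE
  u <- c(u_patent = fixture$utilities$u_patent$base,
         u_uti = fixture$utilities$u_uti$base,
         u_failed = fixture$utilities$u_failed$base)
  df <- discount_factor(tr$cycle, fixture$settings$discount_rate_annual)
  val <- (tr$Patent * u[1] + tr$PatentUTI * u[2] + tr$Failed * u[3]) / 12 * df
  for (m in c(12, 60)) {
    start_sum <- sum(val[tr$cycle <= m - 1])
    end_sum <- sum(val[tr$cycle >= 1 & tr$cycle <= m])
    hcc <- accrue(tr, inp_hcc)$qalys[fixture$settings$reporting_horizons == m]
    nohcc <- accrue(tr, inp_nohcc)$qalys[fixture$settings$reporting_horizons == m]
    expect_equal(nohcc, start_sum)
    expect_true(hcc > end_sum && hcc < start_sum)
    expect_equal(hcc, (start_sum + end_sum) / 2, tolerance = 1e-12)
  }
})

test_that("discounting never increases totals for non-negative flows", {
  inp0 <- fixture
  inp0$settings$discount_rate_annual <- 0
  for (nm in c("JJ", "Resonance")) {
    disc <- accrue(run_cohort(fixture, nm), fixture)
    undisc <- accrue(run_cohort(inp0, nm), inp0)
    expect_true(all(disc$cost <= undisc$cost))
    expect_true(all(disc$qalys <= undisc$qalys))
    expect_true(all(disc$lys <= undisc$lys))
  }
})

test_that("outcomes at 12 months equal those of a 12-cycle run", {
  short <- fixture
  short$settings <- model_settings(horizon = 12, reporting_horizons = 12)
  long_out <- compare_strategies(fixture)
  short_out <- compare_strategies(short)
  for (col in c("cost_JJ", "qalys_JJ", "stents_JJ", "delta_cost",
                "delta_qalys", "nmb")) {
    expect_equal(short_out[[col]], long_out[[col]][long_out$horizon == 12],
                 tolerance = 1e-12)
  }
})

test_that("icer classifies the four quadrants and guards division", {
  expect_identical(icer(-2164.74, 0.046)$label, "dominant")
  expect_identical(icer(500, -0.01)$label, "dominated")
  expect_identical(icer(5, 0)$label, "undefined")
  expect_equal(icer(100, 0.01)$value, 10000)
  expect_equal(icer(-100, -0.01)$value, 10000)  # southwest: a real ratio
})

test_that("nmb follows the formula and is linear in willingness to pay", {
  expect_equal(nmb(-2164.74, 0.046, 20000), 3084.74)
  expect_equal(nmb(100, 0.01, 0), -100)
  w <- seq(0, 50000, by = 10000)
  vals <- nmb(-500, 0.02, w)
  expect_equal(diff(vals) / 10000, rep(0.02, length(w) - 1))
})

test_that("icer and nmb agree on cost-effectiveness classification", {
  set.seed(8)
  for (i in 1:200) {
    dc <- runif(1, -3000, 3000); dq <- runif(1, -0.1, 0.1)
    w <- runif(1, 0, 50000)
    ic <- icer(dc, dq)
    positive_nmb <- nmb(dc, dq, w) > 0
    implied <- (ic$label == "dominant") ||
      (dq > 0 && ic$label == "icer" && ic$value < w) ||
      (dq < 0 && ic$label == "icer" && ic$value > w) ||
      (ic$label == "undefined" && dc < 0)
    expect_identical(positive_nmb, implied)
  }
})

test_that("accrued cost and QALYs agree with the microsimulation oracle", {
  for (nm in c("JJ", "Resonance")) {
    acc <- accrue(run_cohort(fixture, nm), fixture)
    ms <- microsim_oracle(fixture, nm, n = 30000, seed = 77)
    expect_lt(abs(acc$cost[4] - ms$economics$mean[1]),
              3 * ms$economics$se[1])
    expect_lt(abs(acc$qalys[4] - ms$economics$mean[2]),
              3 * ms$economics$se[2])
  }
})

test_that("missing cost entries are rejected by name", {
  broken <- fixture
  broken$costs$gp_visit <- NULL
  expect_error(accrue(run_cohort(fixture, "JJ"), broken), "gp_visit")
})
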