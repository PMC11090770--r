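test_that("transition matrix has the documented structure", {
  # all probabilities zero: alive states stay put, Dead absorbing
  M0 <- build_transition_matrix(list(p_fail = 0, p_uti = 0, p_death = 0,
                                     p_uti_resolve = 1))
  expect_equal(M0["Patent", ], c(Patent = 1, PatentUTI = 0, Failed = 0,
                                 Dead = 0))
  expect_equal(M0["Dead", ], c(Patent = 0, PatentUTI = 0, Failed = 0,
                               Dead = 1))

  # the base-case Patent -> Dead entry is the all-cause monthly mortality
  cl <- list(p_fail = 0.3648, p_uti = 0.0085, p_death = 0.0505,
             p_uti_resolve = 1 / 1.1)
  M <- build_transition_matrix(cl)
  expect_equal(unname(M["Patent", "Dead"]), 0.0505)
  # stent failure applies in all alive states
  expect_equal(unname(M[c("Patent", "PatentUTI", "Failed"), "Failed"]),
               rep(0.3648, 3))
  # a failed stent is replaced like-for-like: fresh-stent risks
  expect_equal(M["Failed", ], M["Patent", ])

  expect_error(build_transition_matrix(
    list(p_fail = 0.7, p_uti = 0.2, p_death = 0.2, p_uti_resolve = 1)),
    "exceeds 1")
  expect_error(build_transition_matrix(
    list(p_fail = -0.1, p_uti = 0, p_death = 0, p_uti_resolve = 1)),
    "\\[0, 1\\]")
})

test_that("rows are stochastic for many random valid parameter sets", {
  set.seed(1)
  for (i in 1:2000) {
    M <- build_transition_matrix(random_clinical())
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0))
  }
})

test_that("an event-free cohort stays patent and uses a single stent", {
  inp <- inert_inputs()
  tr <- run_cohort(inp, "Resonance")
  expect_equal(tr$Patent, rep(1, 61))
  expect_equal(stents_used(tr, 60)$total, 1)
  expect_equal(sum(tr$uti_episodes) + sum(tr$deaths), 0)
})

test_that("occupancy is conserved and death is absorbing along the trace", {
  set.seed(2)
  for (i in 1:25) {
    cl <- random_clinical()
    tr <- run_cohort(fixture, "JJ", clinical = cl)
    occ <- as.matrix(tr[, c("Patent", "PatentUTI", "Failed", "Dead")])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
    expect_true(all(diff(tr$Dead) >= -1e-15))
    expect_true(all(occ >= -1e-15))
    # cumulative deaths equal the Dead occupancy
    expect_equal(cumsum(tr$deaths), tr$Dead, tolerance = 1e-12)
  }
})

test_that("stent use rises with failure risk and falls with mortality", {
  at <- function(f, d) {
    cl <- list(p_fail = f, p_uti = 0.02, p_death = d, p_uti_resolve = 1 / 1.1)
    stents_used(run_cohort(fixture, "JJ", clinical = cl), 60)$total
  }
  f_grid <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(vapply(f_grid, at, numeric(1), d = 0.05)) > 0))
  d_grid <- seq(0.01, 0.4, by = 0.05)
  expect_true(all(diff(vapply(d_grid, at, numeric(1), f = 0.3)) < 0))
})

test_that("unplanned exchanges match the closed form without UTI or planned changes", {
  set.seed(3)
  inp <- inert_inputs()
  for (i in 1:20) {
    f <- runif(1, 0.05, 0.6); d <- runif(1, 0.01, 0.3)
    cl <- list(p_fail = f, p_uti = 0, p_death = d, p_uti_resolve = 1)
    tr <- run_cohort(inp, "JJ", clinical = cl)
    for (m in c(12, 60)) {
      # survivors decline at (1 - d) per cycle; failures are counted for
      # transitions 1 .. m - 1
      expected <- 1 + f * sum((1 - d)^(0:(m - 2)))
      expect_equal(stents_used(tr, m)$total, expected, tolerance = 1e-9)
    }
  }
})

test_that("planned exchanges apply the whole-interval survivor factor", {
  # no deaths or UTIs: planned exchange mass at cycle k is (1 - f)^k
  inp <- inert_inputs()
  f <- 0.1
  cl <- list(p_fail = f, p_uti = 0, p_death = 0, p_uti_resolve = 1)
  inp$strategies$Resonance$planned_exchange_interval <- 12L
  tr <- run_cohort(inp, "Resonance", clinical = cl)
  expect_equal(tr$planned_exchanges[tr$cycle == 12],
               (tr$Patent[tr$cycle == 12] + tr$PatentUTI[tr$cycle == 12]) *
                 (1 - f)^12)
  # the month-12 planned change is performed just outside a 12-month report
  expect_equal(stents_used(tr, 12)$planned, 0)
  expect_gt(stents_used(tr, 13)$planned, 0)
})

test_that("microsimulation is deterministic given a seed and degenerates correctly", {
  inp <- inert_inputs(horizon = 24)
  ms <- microsim_oracle(inp, "JJ", n = 1, seed = 5)
  expect_equal(ms$stents$total, rep(1, 2))
  expect_equal(unname(ms$occupancy[, "Patent"]), rep(1, 25))

  a <- microsim_oracle(fixture, "JJ", n = 500, seed = 99)
  b <- microsim_oracle(fixture, "JJ", n = 500, seed = 99)
  expect_identical(a, b)
  c2 <- microsim_oracle(fixture, "JJ", n = 500, seed = 100)
  expect_false(identical(a$stents$total, c2$stents$total))
})

test_that("cohort engine agrees with the microsimulation oracle", {
  set.seed(6)
  n <- 40000
  for (i in 1:2) {
    cl <- random_clinical()
    nm <- c("JJ", "Resonance")[i]
    tr <- run_cohort(fixture, nm, clinical = cl)
    ms <- microsim_oracle(fixture, nm, n = n, seed = 1000 + i, clinical = cl)
    hz <- fixture$settings$reporting_horizons
    occ <- as.matrix(tr[tr$cycle %in% hz,
                        c("Patent", "PatentUTI", "Failed", "Dead")])
    z <- abs(occ - ms$occupancy[hz + 1, ]) /
      pmax(ms$occupancy_se[hz + 1, ], 1 / n)
    expect_lt(max(z), 3)
    for (j in seq_along(hz)) {
      expect_lt(abs(stents_used(tr, hz[j])$total - ms$stents$total[j]),
                3 * ms$stents$se[j] + 1e-9)
    }
    expect_lt(abs(sum(tr$uti_episodes) - ms$events$mean[1]),
              3 * ms$events$se[1] + 1e-9)
    expect_lt(abs(tr$Dead[61] - ms$events$mean[2]), 3 * ms$events$se[2])
  }
})
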