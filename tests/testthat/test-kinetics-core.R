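test_that("generator matrices have the published three-state structure", {
  r <- p26_rates()
  Rf <- build_rate_matrix(r, conc = 10, variant = "full")
  expect_equal(colSums(Rf), rep(0, 3), tolerance = 1e-12)
  # no binding at zero concentration: the 2->3 entry vanishes
  R0 <- build_rate_matrix(r, conc = 0, variant = "full")
  expect_identical(R0[3, 2], 0)
  # binding variant: state 3 absorbing, third column all zero
  Rb <- build_rate_matrix(r, conc = 10, variant = "binding")
  expect_identical(Rb[, 3], c(0, 0, 0))
  expect_equal(Rb[3, 2], r$k23 * 10)
  # release variant: state 1 absorbing
  Rr <- build_rate_matrix(r, conc = 10, variant = "release")
  expect_identical(Rr[, 1], c(0, 0, 0))
  expect_equal(Rr[2, 3], r$k32)
  # conservation holds for random rate sets
  set.seed(4)
  for (i in 1:20) {
    rr <- rate_set(runif(1, 0, 5), runif(1, 10, 200), runif(1, 0, 10),
                   runif(1, 0, 3))
    M <- build_rate_matrix(rr, runif(1, 0, 500), "full")
    expect_lt(max(abs(colSums(M))), 1e-12)
  }
  expect_error(build_rate_matrix(r, conc = -1), "conc")
  expect_error(rate_set(-1, 100, 1, 1), "k12")
})

test_that("closed-form transition rates match the eigendecomposition oracle", {
  # frozen closed-form values
  expect_equal(k_high_to_low(2.5, 0.11, 10), 0.7638889, tolerance = 1e-6)
  expect_equal(k_low_to_high(1.03, 0.004, 0.9, 500), 0.3196552,
               tolerance = 1e-6)
  # independent oracle: slowest nonzero eigenvalue of the absorbing matrices
  slowest <- function(M) {
    ev <- Re(eigen(M, only.values = TRUE)$values)
    min(abs(ev[abs(ev) > 1e-9]))
  }
  Rb <- build_rate_matrix(p26_rates(), 10, "binding")
  expect_equal(slowest(Rb), k_high_to_low(2.5, 0.11, 10), tolerance = 0.02)
  Rr <- build_rate_matrix(p36_rates(), 500, "release")
  expect_equal(slowest(Rr), k_low_to_high(1.03, 0.004, 0.9, 500),
               tolerance = 0.01)
  # limits
  expect_identical(k_high_to_low(2.5, 0.11, 0), 0)
  expect_equal(k_high_to_low(2.5, 0.11, 1e9), 2.5, tolerance = 1e-6)
  expect_equal(k_high_to_low(2.5, 0.11, 1e-4), 0.11 * 1e-4, tolerance = 1e-4)
  expect_identical(k_low_to_high(0.66, 0.11, 2.5, 0), 0.66)
  # hyperbolic tail of the low->high rate
  expect_equal(k_low_to_high(0.66, 0.11, 2.5, 1e6),
               0.66 * 2.5 / (0.11 * 1e6), tolerance = 1e-3)
})

test_that("closed forms agree with eigenvalues to 2% deep in the regime", {
  set.seed(7)
  slowest <- function(M) {
    ev <- Re(eigen(M, only.values = TRUE)$values)
    min(abs(ev[abs(ev) > 1e-9]))
  }
  for (i in 1:100) {
    k21 <- runif(1, 50, 300)
    conc <- runif(1, 10, 500)
    k23 <- runif(1, 0.5, 5)
    k12 <- min(k21, k23 * conc) / runif(1, 50, 500)
    r <- rate_set(k12, k21, k23, runif(1, 0.1, 2))
    kon <- r$kon_eff
    Rb <- build_rate_matrix(r, conc, "binding")
    expect_equal(slowest(Rb), k_high_to_low(k12, kon, conc),
                 tolerance = 0.02)
  }
  # spectral_solution's own deep-regime example: 1e-3 relative agreement
  r <- rate_set(0.01, 100, 1, 0)
  sol <- spectral_solution(build_rate_matrix(r, 50, "binding"))
  lam <- Re(sol$eigenvalues)
  lam_slow <- min(abs(lam[abs(lam) > 1e-9]))
  expect_equal(lam_slow, 0.01 / (1 + 100 / 50), tolerance = 1e-3)
})

test_that("spectral solution reconstructs the propagated distribution", {
  r <- p26_rates()
  for (variant in c("full", "binding", "release")) {
    M <- build_rate_matrix(r, 10, variant)
    sol <- spectral_solution(M, x0 = c(1, 0, 0))
    expect_false(sol$defective)
    # one eigenvalue exactly zero, all real parts <= 0
    expect_true(any(sol$eigenvalues == 0))
    expect_true(all(Re(sol$eigenvalues) <= 1e-12))
    for (tt in c(0, 0.05, 0.5, 5)) {
      direct <- propagate_master_equation(M, c(1, 0, 0), tt)
      recon <- Re(sol$coefficients %*% exp(sol$eigenvalues * tt))
      expect_equal(unlist(direct[1, c("p1", "p2", "p3")], use.names = FALSE),
                   pmin(pmax(as.numeric(recon), 0), 1), tolerance = 1e-8)
    }
  }
  # binding variant lambda- ~ -(k21 + k23 c)
  sol <- spectral_solution(build_rate_matrix(r, 10, "binding"))
  expect_equal(min(Re(sol$eigenvalues)), -(r$k21 + r$k23 * 10),
               tolerance = 0.02)
})

test_that("master-equation propagation conserves probability and hits limits", {
  r <- p26_rates()
  M <- build_rate_matrix(r, 10, "full")
  out <- propagate_master_equation(M, c(1, 0, 0), c(0, 0.1, 1, 10, 100))
  expect_equal(out$p1 + out$p2 + out$p3, rep(1, 5), tolerance = 1e-9)
  # t = 0 returns x0
  expect_equal(unlist(out[1, c("p1", "p2", "p3")], use.names = FALSE),
               c(1, 0, 0))
  # binding variant absorbs everything into state 3: N3 = 1 - exp(lambda+ t)
  Rb <- build_rate_matrix(r, 10, "binding")
  long <- propagate_master_equation(Rb, c(1, 0, 0), 200)
  expect_equal(long$p3, 1, tolerance = 1e-6)
  mid <- propagate_master_equation(Rb, c(1, 0, 0), 1)
  expect_equal(mid$p3, 1 - exp(-k_high_to_low(2.5, 0.11, 10)), tolerance = 0.02)
  expect_error(propagate_master_equation(matrix(1, 3, 3), c(1, 0, 0), 1),
               "generator")
})

test_that("propagation matches Gillespie occupancy within Monte-Carlo error", {
  r <- p26_rates()
  n <- 4000
  states <- withr::with_seed(99, {
    vapply(seq_len(n), function(i) {
      p <- simulate_state_path(r, conc = 10, duration = 1, start_state = 1L)
      p$state[nrow(p)]
    }, integer(1))
  })
  emp <- tabulate(states, 3) / n
  se <- sqrt(pmax(emp * (1 - emp), 1e-6) / n)
  M <- build_rate_matrix(r, 10, "full")
  theo <- propagate_master_equation(M, c(1, 0, 0), 1)
  theo <- unlist(theo[1, c("p1", "p2", "p3")], use.names = FALSE)
  expect_true(all(abs(emp - theo) <= 3 * se + 1e-3))
})

test_that("apparent rates are monotone in concentration", {
  set.seed(12)
  for (i in 1:25) {
    k12 <- runif(1, 0.1, 5); kon <- runif(1, 1e-4, 0.5)
    k32 <- runif(1, 0.1, 3)
    cc <- sort(runif(6, 0.1, 1000))
    expect_true(all(diff(k_high_to_low(k12, kon, cc)) > 0))
    expect_true(all(diff(k_low_to_high(k32, kon, k12, cc)) < 0))
    expect_true(all(k_high_to_low(k12, kon, cc) < k12))
  }
})

test_that("the exposed-unbound intermediate is barely populated at stationarity", {
  r <- p26_rates()
  M <- build_rate_matrix(r, 10, "full")
  ev <- eigen(M)
  v <- Re(ev$vectors[, which.min(abs(ev$values))])
  v <- v / sum(v)
  expect_lt(v[2], r$k12 / r$k21)
  expect_lt(v[2], 0.01)
})

test_that("rate-set invariants and regime metrics are exact arithmetic", {
  r <- rate_set(2.5, 100, 4.4, 0.66)
  expect_equal(r$kon_eff, 2.5 * 4.4 / 100, tolerance = 1e-12)
  expect_true(r$regime_valid)
  expect_false(rate_set(200, 100, 1, 1)$regime_valid)

  m26 <- regime_metrics(effective_params(2.5, 0.66, 0.11))
  expect_equal(m26$KD_eff, 6.0, tolerance = 1e-6)
  expect_equal(m26$c_cross, 22.72727, tolerance = 1e-6)
  expect_equal(m26$regime_ratio, 0.264, tolerance = 1e-3)

  m31 <- regime_metrics(effective_params(0.9, 0.83, 0.0008))
  expect_equal(m31$KD_eff, 1037.5, tolerance = 1e-6)
  expect_equal(m31$c_cross, 1125, tolerance = 1e-6)
  expect_equal(m31$regime_ratio, 0.83 / 0.9, tolerance = 1e-9)

  expect_equal(regime_metrics(effective_params(1.3, 1.3, 0.01))$regime_ratio,
               1)
  expect_error(regime_metrics(effective_params(1, 1, 0)), "kon_eff")
})
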