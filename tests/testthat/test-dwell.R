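fake_ideal <- function(labels, frame_time = 0.1) {
  n <- length(labels)
  tibble::tibble(frame = seq_len(n), time_s = (seq_len(n) - 1) * frame_time,
                 fret_e = ifelse(labels == "high", 0.75, 0.15),
                 label = labels)
}

test_that("dwell extraction is exact run-length arithmetic with edge censoring", {
  dw <- extract_dwells(fake_ideal(c("high", "high", "high", "low", "low",
                                    "high", "high")), frame_time = 0.1)
  high <- dw[dw$state == "high", ]
  low <- dw[dw$state == "low", ]
  expect_equal(high$duration_s, c(0.3, 0.2), tolerance = 1e-12)
  expect_true(all(high$censored))
  expect_equal(low$duration_s, 0.2, tolerance = 1e-12)
  expect_false(low$censored)
  expect_equal(attr(dw, "t_min"), 0.2, tolerance = 1e-12)
  # no transitions: empty and flagged
  empty <- extract_dwells(fake_ideal(rep("high", 30)), 0.1)
  expect_identical(nrow(empty), 0L)
  expect_true(attr(empty, "empty"))
})

test_that("single-exponential MLE has the stated closed forms", {
  d <- c(0.4, 1.1, 2.7, 0.9, 5.0, 1.3, 0.6, 2.2, 0.8, 1.9)
  fit <- fit_exponential_mle(d, n_components = 1, t_min = 0)
  expect_equal(fit$rates, 1 / mean(d), tolerance = 1e-12)
  # left-truncated closed form
  big <- withr::with_seed(1, stats::rexp(10000, 0.66))
  big <- big[big >= 0.2]
  fit_t <- fit_exponential_mle(big, n_components = 1, t_min = 0.2)
  expect_equal(fit_t$rates, 1 / (mean(big) - 0.2), tolerance = 1e-12)
  # and the truncated estimator is unbiased: within 3 analytic SE of truth
  expect_lt(abs(fit_t$rates - 0.66), 3 * 0.66 / sqrt(length(big)))
  expect_error(fit_exponential_mle(d[1:5], 1), "at least 10")
})

test_that("two-component MLE recovers a well-separated mixture", {
  d <- withr::with_seed(10, {
    pick <- runif(2000) < 0.7
    ifelse(pick, stats::rexp(2000, 2.0), stats::rexp(2000, 0.3))
  })
  fit <- fit_exponential_mle(d, n_components = 2, t_min = 0)
  expect_equal(fit$rates[1], 2.0, tolerance = 0.15)
  expect_equal(fit$rates[2], 0.3, tolerance = 0.15)
  expect_equal(fit$amplitudes[1], 0.7, tolerance = 0.15)
  expect_gt(fit$rates[1], fit$rates[2])
  expect_equal(sum(fit$amplitudes), 1, tolerance = 1e-9)
})

test_that("likelihood-ratio selection controls errors and honours ties", {
  # ties (and any non-improvement) go to the simpler model
  f1 <- fit_exponential_mle(withr::with_seed(2, stats::rexp(200, 1)), 1, 0)
  f2 <- f1
  f2$n_components <- 2L
  f2$rates <- c(f1$rates, f1$rates / 2)
  f2$amplitudes <- c(1, 0)
  chosen <- select_dwell_model(f1, f2)
  expect_identical(chosen$n_components, 1L)

  sel <- function(d) {
    g1 <- fit_exponential_mle(d, 1, 0)
    g2 <- fit_exponential_mle(d, 2, 0)
    select_dwell_model(g1, g2)$n_components
  }
  # type-I control on single-exponential data
  null_picks <- withr::with_seed(33, {
    vapply(1:100, function(i) sel(stats::rexp(1000, 1.0)), integer(1))
  })
  expect_gte(mean(null_picks == 1L), 0.90)
  # power on a well-separated mixture
  alt_picks <- withr::with_seed(34, {
    vapply(1:100, function(i) {
      pick <- runif(1000) < 0.6
      sel(ifelse(pick, stats::rexp(1000, 5.0), stats::rexp(1000, 0.2)))
    }, integer(1))
  })
  expect_gte(mean(alt_picks == 2L), 0.95)
})

test_that("a minor contaminant component does not displace the primary rate", {
  d <- withr::with_seed(11, {
    pick <- runif(3000) < 0.92
    ifelse(pick, stats::rexp(3000, 0.8), stats::rexp(3000, 4.0))
  })
  fit <- fit_exponential_mle(d, n_components = 2, t_min = 0)
  primary <- fit$rates[which.max(fit$amplitudes)]
  expect_equal(primary, 0.8, tolerance = 0.15)
})

test_that("censoring policies behave as their likelihoods dictate", {
  # fixed right-censoring (a bleach-like observation cutoff): censored
  # dwells are genuinely truncated, the two policies disagree, and the
  # survival likelihood recovers the generating rate
  rate <- 0.5; cutoff <- 3
  full <- withr::with_seed(12, stats::rexp(4000, rate))
  sim <- tibble::tibble(
    state = "x",
    duration_s = pmin(full, cutoff),
    censored = full > cutoff
  )
  excl <- fit_exponential_mle(sim, 1, t_min = 0)
  surv <- fit_exponential_mle(sim, 1, t_min = 0, use_censored = TRUE)
  naive_rate <- 1 / mean(sim$duration_s)
  expect_false(isTRUE(all.equal(excl$rates, naive_rate, tolerance = 0.01)))
  # survival MLE = events / total observed time, unbiased
  expect_equal(surv$rates,
               sum(!sim$censored) / sum(sim$duration_s), tolerance = 1e-9)
  expect_lt(abs(surv$rates - rate),
            3 * surv$rates / sqrt(sum(!sim$censored)))
  # in long observation windows the default exclusion policy is consistent
  T <- 200
  win <- withr::with_seed(13, {
    purrr::map(1:60, function(i) {
      t <- 0; out <- numeric(); cen <- logical()
      while (t < T) {
        d <- stats::rexp(1, rate)
        obs <- min(d, T - t)
        out <- c(out, obs); cen <- c(cen, t + d > T)
        t <- t + d
      }
      cen[1] <- TRUE
      tibble::tibble(state = "x", duration_s = out, censored = cen)
    }) |> dplyr::bind_rows()
  })
  wfit <- fit_exponential_mle(win, 1, t_min = 0)
  expect_lt(abs(wfit$rates - rate), 3 * wfit$rates / sqrt(wfit$n))
})

test_that("pooled per-concentration rates are consistent and reproducible", {
  dwt <- withr::with_seed(14, {
    purrr::map(1:40, function(i) {
      nh <- 12
      tibble::tibble(
        trace_id = sprintf("t%02d", i), conc_nM = 5,
        state = rep(c("high", "low"), each = nh),
        duration_s = c(stats::rexp(nh, 0.45), stats::rexp(nh, 0.54)),
        censored = FALSE
      )
    }) |> dplyr::bind_rows()
  })
  attr(dwt, "t_min") <- 0
  rp <- rates_at_concentration(dwt, bootstrap_reps = 100, seed = 5)
  expect_equal(rp$kHL, 1 / mean(dwt$duration_s[dwt$state == "high"]),
               tolerance = 1e-9)
  expect_lt(abs(rp$kHL - 0.45), 3 * rp$kHL_se)
  expect_lt(abs(rp$kLH - 0.54), 3 * rp$kLH_se)
  rp2 <- rates_at_concentration(dwt, bootstrap_reps = 100, seed = 5)
  expect_identical(rp, rp2)
  rp3 <- rates_at_concentration(dwt, bootstrap_reps = 100, seed = 6)
  expect_false(identical(rp$kHL_se, rp3$kHL_se))
})

test_that("a full simulated cohort yields dwells matching the generator", {
  r <- p26_rates()
  coh <- small_cohort(r, concs = 10, n = 40, duration = 120, seed = 71)
  dw <- extract_dwells_cohort(idealize_cohort(coh))
  low <- dw[dw$state == "low" & !dw$censored & dw$duration_s >= 0.2, ]
  # apparent low->high rate at 10 nM (TF can rebind before rewrap)
  k_apparent <- k_low_to_high(0.66, 0.11, 2.5, 10)
  est <- 1 / (mean(low$duration_s) - 0.2)
  expect_equal(est, k_apparent, tolerance = 0.12)
})
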