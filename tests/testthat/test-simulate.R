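test_that("state paths respect edges, seeds, and zero-concentration limits", {
  r <- p26_rates()
  p1 <- simulate_state_path(r, conc = 10, duration = 60, seed = 5)
  p2 <- simulate_state_path(r, conc = 10, duration = 60, seed = 5)
  expect_identical(p1, p2)
  # allowed edges only, strictly increasing entry times from 0
  expect_identical(p1$entry_time[1], 0)
  expect_true(all(diff(p1$entry_time) > 0))
  steps <- abs(diff(p1$state))
  expect_true(all(steps == 1))
  # no binding without TF
  p0 <- simulate_state_path(r, conc = 0, duration = 120, seed = 6)
  expect_false(any(p0$state == 3))
  # absorbing flag when every exit rate vanishes
  dead <- rate_set(1, 100, 1, 0)      # state 3 inescapable
  pa <- simulate_state_path(dead, conc = 50, duration = 50, seed = 7)
  expect_true(attr(pa, "absorbed"))
  expect_identical(pa$state[nrow(pa)], 3L)
})

test_that("simulated holding times recover the generating rates", {
  r <- p26_rates()
  # long windows keep the complete-dwell selection bias (~ mean/duration)
  # well below Monte-Carlo resolution
  dwells <- withr::with_seed(42, {
    purrr::map(1:60, function(i) {
      p <- simulate_state_path(r, conc = 10, duration = 400)
      d <- diff(c(p$entry_time, attr(p, "duration")))
      # drop the final (censored) holding interval
      tibble::tibble(state = p$state[-nrow(p)], dur = d[-length(d)])
    }) |> dplyr::bind_rows()
  })
  # state 3 dwell mean = 1/k32 (bound lifetime)
  d3 <- dwells$dur[dwells$state == 3]
  expect_gt(length(d3), 500)
  expect_lt(abs(mean(d3) - 1 / 0.66), 3 * sd(d3) / sqrt(length(d3)))
  # state 1 exit rate = k12
  d1 <- dwells$dur[dwells$state == 1]
  expect_lt(abs(mean(d1) - 1 / 2.5), 3 * sd(d1) / sqrt(length(d1)))
  # state 2 exit rate = k21 + k23*conc
  d2 <- dwells$dur[dwells$state == 2]
  tot2 <- r$k21 + r$k23 * 10
  expect_lt(abs(mean(d2) - 1 / tot2), 3 * sd(d2) / sqrt(length(d2)))
})

test_that("frame rendering is the exact occupancy-weighted average", {
  em <- quiet_emission()
  # no intra-frame transitions: frames sit exactly at the emission levels
  p <- manual_path(c(0, 0.2, 0.4), c(1, 3, 1), duration = 0.6)
  tr <- render_fret_trace(p, em, seed = 1)
  expect_equal(tr$fret_e, c(0.75, 0.75, 0.15, 0.15, 0.75, 0.75),
               tolerance = 1e-9)
  # half a frame in state 1, half in state 3 -> midpoint
  p2 <- manual_path(c(0, 0.05), c(1, 3), duration = 0.1)
  tr2 <- render_fret_trace(p2, em, seed = 1)
  expect_equal(tr2$fret_e, (0.75 + 0.15) / 2, tolerance = 1e-9)
  # occupancy conservation: frame-summed emission equals the path integral
  p3 <- manual_path(c(0, 0.13, 0.31, 0.55), c(1, 2, 3, 1), duration = 1.0)
  tr3 <- render_fret_trace(p3, em, seed = 1)
  integral <- 0.75 * 0.13 + 0.15 * (0.31 - 0.13) + 0.15 * (0.55 - 0.31) +
    0.75 * (1.0 - 0.55)
  expect_equal(sum(tr3$fret_e) * em$frame_time, integral, tolerance = 1e-9)
})

test_that("sub-frame unbound excursions are invisible at camera resolution", {
  # a 1->2->1 excursion of duration dt shifts one frame by
  # (e_high - e_low) * dt / frame_time; with k21 = 100 s^-1 the expected
  # shift is 0.6 * 0.01 / 0.1 = 0.06 < noise_sd = 0.08, and the analytic
  # detectable fraction P(shift > 3 * noise_sd) = exp(-4) = 1.8%
  em <- emission_model()
  durs <- withr::with_seed(31, stats::rexp(10000, rate = 100))
  shift <- (em$e_high - em$e_low) * durs / em$frame_time
  expect_lt(mean(shift), em$noise_sd)
  frac <- mean(shift > 3 * em$noise_sd)
  expect_equal(frac, exp(-4), tolerance = 0.25)
  expect_lt(frac, 0.025)
})

test_that("cohort simulation is labelled, sized, and reproducible", {
  r <- p26_rates()
  coh <- simulate_experiment(r, conc_list = c(1, 5), n_traces = 4,
                             duration = 20, seed = 77)
  expect_identical(sort(unique(coh$conc_nM)), c(1, 5))
  expect_identical(nrow(dplyr::distinct(coh, trace_id, conc_nM)), 8L)
  expect_identical(nrow(coh), 8L * 200L)
  coh2 <- simulate_experiment(r, conc_list = c(1, 5), n_traces = 4,
                              duration = 20, seed = 77)
  expect_identical(coh, coh2)
  expect_error(simulate_experiment(r, numeric(), 4, 20), "conc_list")
})

test_that("higher TF concentration increases low-FRET occupancy", {
  r <- p36_rates()
  coh <- simulate_experiment(r, conc_list = c(50, 500), n_traces = 15,
                             duration = 60, seed = 13)
  frac_low <- coh |>
    dplyr::group_by(conc_nM) |>
    dplyr::summarise(f = mean(fret_e < 0.45)) |>
    dplyr::arrange(conc_nM)
  expect_gt(frac_low$f[2], frac_low$f[1])
})

test_that("titration generator hits exact values and inverts cleanly", {
  # zero concentration, noiseless -> E0
  t0 <- generate_titration(4.3, 0.4, e0 = 0.7, conc_grid = c(0, 4.3, 100),
                           noise_sd = 1e-12, replicates = 1, seed = 2)
  expect_equal(t0$fret_e[t0$conc_nM == 0], 0.7, tolerance = 1e-9)
  # half-saturation identity at conc = S
  expect_equal(t0$fret_e[t0$conc_nM == 4.3], 0.7 - 0.4 / 2, tolerance = 1e-9)
  # two-event curve is monotone decreasing across a log grid
  grid <- 10^seq(-1, log10(3000), length.out = 40)
  tt <- generate_titration(c(2.1, 380), c(0.25, 0.2), e0 = 0.7,
                           conc_grid = grid, noise_sd = 1e-12,
                           replicates = 1, seed = 3)
  expect_true(all(diff(tt$fret_e) < 0))
  # spans both transitions
  expect_gt(tt$fret_e[1] - tt$fret_e[40], 0.35)
  # determinism and validation
  a <- generate_titration(4.3, 0.4, seed = 9)
  b <- generate_titration(4.3, 0.4, seed = 9)
  expect_identical(a, b)
  expect_error(generate_titration(4.3, 0.9, e0 = 0.5), "amplitudes")
  # noiseless curves refit to the generating parameters
  fit <- fit_isotherm(generate_titration(4.3, 0.4, e0 = 0.7,
                                         noise_sd = 1e-12, replicates = 1,
                                         seed = 4), n_events = 1)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["S1"]), 4.3, tolerance = 1e-6)
  expect_equal(unname(est["dE1"]), 0.4, tolerance = 1e-6)
  expect_equal(unname(est["e0"]), 0.7, tolerance = 1e-6)
})
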