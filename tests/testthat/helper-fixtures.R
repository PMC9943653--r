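# Ground-truth rate sets used throughout the tests.  kon_eff values are the
# published global-fit triples; k21 is fixed at 100 s^-1 (rewrapping on the
# 10 ms scale) and k23 follows from kon_eff = (k12/k21) * k23.
p26_rates <- function() rate_set(k12 = 2.5, k21 = 100,
                                 k23 = 0.11 * 100 / 2.5, k32 = 0.66)
p31_rates <- function() rate_set(k12 = 0.9, k21 = 100,
                                 k23 = 0.0008 * 100 / 0.9, k32 = 0.83)
p36_rates <- function() rate_set(k12 = 0.9, k21 = 100,
                                 k23 = 0.004 * 100 / 0.9, k32 = 1.03)

# Published ensemble half-saturation values (nM), specific first event.
ensemble_s12 <- function() {
  tibble::tibble(
    label = c("P19", "P21", "P23", "P26", "P29", "P31", "P33", "P36"),
    inner_bp = c(19, 21, 23, 26, 29, 31, 33, 36),
    value = c(0.7, 0.6, 2.1, 4.3, 1.7, 500, 240, 290),
    se = c(0.3, 0.2, 0.3, 0.2, 0.1, 100, 90, 30)
  )
}

# A small simulated cohort, idealized, for reuse across tests.
small_cohort <- function(rates = p26_rates(), concs = c(2, 5, 10),
                         n = 20, duration = 60, seed = 101) {
  simulate_experiment(rates, concs, n_traces = n, duration = duration,
                      seed = seed)
}

# Hand-built state path with explicit attributes, for rendering tests.
manual_path <- function(entry_time, state, duration, conc = 0) {
  out <- tibble::tibble(entry_time = entry_time, state = as.integer(state))
  attr(out, "duration") <- duration
  attr(out, "conc") <- conc
  attr(out, "absorbed") <- FALSE
  class(out) <- c("se_path", class(out))
  out
}

# Noise-free emission helper (noise_sd must be > 0 by contract; tests that
# need exact levels use a vanishingly small sd instead).
quiet_emission <- function(frame_time = 0.1) {
  emission_model(noise_sd = 1e-12, frame_time = frame_time)
}
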