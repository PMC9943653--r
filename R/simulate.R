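#' Camera emission model for simulated FRET traces
#'
#' Two FRET efficiency levels with Gaussian per-frame noise: state 1
#' (wrapped) emits at `e_high`; states 2 and 3 both emit at `e_low`
#' because the unwrapped geometry dominates the dye separation whether or
#' not the TF is bound.  Defaults (`e_high` 0.75, `e_low` 0.15, noise sd
#' 0.08 efficiency units, 0.1 s frames) are explicit, configurable choices
#' typical of prism-TIRF smFRET at ~10 Hz; the efficiency levels
#' themselves are arbitrary because only the two-level separation enters
#' the analysis.
#'
#' @param e_high FRET efficiency of the wrapped state (0-1).
#' @param e_low FRET efficiency of the unwrapped states (0-1, < `e_high`).
#' @param noise_sd Gaussian per-frame noise sd (> 0).
#' @param frame_time Camera frame integration time in seconds (> 0).
#' @return A one-row tibble of class `se_emission`.
#' @export
emission_model <- function(e_high = 0.75, e_low = 0.15,
                           noise_sd = 0.08, frame_time = 0.1) {
  if (!(e_low >= 0 && e_low < e_high && e_high <= 1)) {
    abort("need 0 <= e_low < e_high <= 1")
  }
  check_pos(noise_sd, "noise_sd"); check_pos(frame_time, "frame_time")
  out <- tibble(e_high = e_high, e_low = e_low,
                noise_sd = noise_sd, frame_time = frame_time)
  class(out) <- c("se_emission", class(out))
  out
}

#' Simulate one state path of the three-state chain
#'
#' Exact stochastic (Gillespie) simulation of the continuous-time Markov
#' chain with transitions 1<->2 (rates `k12`, `k21`) and 2<->3 (rates
#' `k23 * conc`, `k32`).  Holding times are exponential with the total
#' exit rate of the current state; the next state is chosen in proportion
#' to the edge rates.
#'
#' @param rates An [rate_set()] row.
#' @param conc TF concentration (nM).
#' @param duration Total simulated time (s, > 0).
#' @param seed Optional integer seed (reproducible paths).
#' @param start_state Initial state; defaults to 1 (wrapped), the
#'   appropriate start when unwrapping is rare.
#' @return A tibble of class `se_path` with columns `entry_time`, `state`,
#'   and attributes `duration`, `conc`, `absorbed` (TRUE when the path
#'   reached a state with zero exit rate and stays there).
#' @export
simulate_state_path <- function(rates, conc, duration, seed = NULL,
                                start_state = 1L) {
  check_nonneg(conc, "conc"); check_pos(duration, "duration")
  stopifnot(start_state %in% 1:3)
  res <- with_seed_or_current(seed, {
    gillespie_path_cpp(rates$k12, rates$k21, rates$k23 * conc, rates$k32,
                       duration, as.integer(start_state))
  })
  out <- tibble(entry_time = res$entry_time, state = as.integer(res$state))
  attr(out, "duration") <- duration
  attr(out, "conc") <- conc
  attr(out, "absorbed") <- res$absorbed
  class(out) <- c("se_path", class(out))
  out
}

#' Render a state path into a camera-binned FRET trace
#'
#' Per-frame efficiency is the occupancy-time-weighted average of the
#' state emission levels within the frame plus Gaussian noise.  With
#' rewrapping on the 10 ms scale and 0.1 s frames, isolated 1 -> 2 -> 1
#' excursions perturb a single frame by less than the noise amplitude in
#' expectation, reproducing the observability constraint of camera-rate
#' smFRET: unbound site exposure is invisible and only TF-trapped
#' unwrapping registers as a low-FRET dwell.
#'
#' @param path An [simulate_state_path()] result.
#' @param emission An [emission_model()] row.
#' @param seed Optional integer seed for the noise draw.
#' @param trace_id Identifier stored with the trace.
#' @return A tibble of class `se_trace` with columns `frame`, `time_s`
#'   (frame start), `fret_e`, and attributes `conc`, `emission`,
#'   `trace_id`.  Efficiencies may leave `[0, 1]` because of noise.
#' @export
render_fret_trace <- function(path, emission, seed = NULL,
                              trace_id = "trace_1") {
  duration <- attr(path, "duration")
  ft <- emission$frame_time
  if (duration < ft) abort("path shorter than one frame")
  levels <- c(emission$e_high, emission$e_low, emission$e_low)
  mean_e <- render_frames_cpp(path$entry_time, path$state, duration, ft,
                              levels)
  e <- with_seed_or_current(seed, {
    mean_e + rnorm(length(mean_e), 0, emission$noise_sd)
  })
  out <- tibble(
    frame = seq_along(e),
    time_s = (seq_along(e) - 1) * ft,
    fret_e = e
  )
  attr(out, "conc") <- attr(path, "conc")
  attr(out, "emission") <- emission
  attr(out, "trace_id") <- trace_id
  class(out) <- c("se_trace", class(out))
  out
}

#' Simulate a per-concentration cohort of FRET traces
#'
#' Generates `n_traces` traces at each concentration in `conc_list`,
#' emulating a single-molecule experiment that images hundreds of
#' individual nucleosomes at each of several TF concentrations.  Per-trace
#' seeds are derived deterministically from the master seed, so any single
#' trace can be regenerated in isolation.
#'
#' @param rates An [rate_set()] row (ground truth).
#' @param conc_list Concentrations in nM (non-empty).
#' @param n_traces Traces per concentration (>= 1).
#' @param duration Trace duration in seconds.
#' @param emission An [emission_model()] row.
#' @param seed Master integer seed.
#' @param start_state Initial chain state, default 1 (wrapped).
#' @return A tidy tibble of class `se_cohort` with columns `trace_id`,
#'   `conc_nM`, `frame`, `time_s`, `fret_e` and an attribute `params`
#'   recording every generation parameter.
#' @export
simulate_experiment <- function(rates, conc_list, n_traces, duration,
                                emission = emission_model(), seed = 1L,
                                start_state = 1L) {
  if (length(conc_list) == 0) abort("`conc_list` must be non-empty.")
  stopifnot(n_traces >= 1)
  grid <- tidyr::expand_grid(conc_nM = conc_list, rep = seq_len(n_traces))
  traces <- purrr::pmap(
    list(grid$conc_nM, grid$rep, seq_len(nrow(grid))),
    function(conc, rep, idx) {
      s <- derive_seed(seed, idx)
      id <- sprintf("c%g_t%03d", conc, rep)
      path <- simulate_state_path(rates, conc, duration, seed = s,
                                  start_state = start_state)
      tr <- render_fret_trace(path, emission, seed = derive_seed(s, 1L),
                              trace_id = id)
      tibble(trace_id = id, conc_nM = conc, frame = tr$frame,
             time_s = tr$time_s, fret_e = tr$fret_e)
    }
  )
  out <- dplyr::bind_rows(traces)
  attr(out, "params") <- list(
    rates = as.list(rates), conc_list = conc_list, n_traces = n_traces,
    duration = duration, emission = as.list(emission), seed = seed,
    start_state = start_state
  )
  class(out) <- c("se_cohort", class(out))
  out
}

#' Generate a noisy ensemble FRET titration
#'
#' Evaluates a one- or two-event binding model
#' `E(c) = E0 - sum_i dE_i * c / (S_i + c)` on a concentration grid and
#' adds Gaussian noise per replicate, emulating ensemble FRET titrations
#' of TF binding.  Defaults: 12-point logarithmic grid from 0.1 to
#' 3000 nM plus a zero point, 3 replicates, noise sd 0.02 efficiency
#' units.
#'
#' @param s_values Half-saturation concentration(s) `S_i` in nM (length 1
#'   or 2, > 0).
#' @param amplitudes FRET amplitude(s) `dE_i` of each event (same length).
#' @param e0 Zero-concentration FRET efficiency.
#' @param conc_grid Concentrations in nM; the default includes 0, which
#'   pins `E0` during fitting.
#' @param noise_sd Gaussian noise sd in efficiency units (>= 0).
#' @param replicates Number of replicate curves.
#' @param seed Optional integer seed.
#' @return A tibble of class `se_titration` with columns `conc_nM`,
#'   `fret_e`, `replicate` and an attribute `params`.
#' @export
generate_titration <- function(s_values, amplitudes, e0 = 0.7,
                               conc_grid = c(0, 10^seq(-1, log10(3000),
                                                       length.out = 12)),
                               noise_sd = 0.02, replicates = 3,
                               seed = NULL) {
  check_pos(s_values, "s_values")
  if (length(amplitudes) != length(s_values) || !length(s_values) %in% 1:2) {
    abort("`s_values` and `amplitudes` must have matching length 1 or 2.")
  }
  check_nonneg(noise_sd, "noise_sd")
  if (e0 - sum(amplitudes) < -1e-12) {
    abort("amplitudes exceed `e0`: efficiency would be negative at saturation.")
  }
  mean_e <- titration_mean(conc_grid, e0, amplitudes, s_values)
  out <- with_seed_or_current(seed, {
    tidyr::expand_grid(replicate = seq_len(replicates),
                       conc_nM = conc_grid) |>
      dplyr::mutate(
        fret_e = rep(mean_e, replicates) +
          rnorm(dplyr::n(), 0, noise_sd)
      ) |>
      dplyr::select("conc_nM", "fret_e", "replicate")
  })
  attr(out, "params") <- list(s_values = s_values, amplitudes = amplitudes,
                              e0 = e0, noise_sd = noise_sd,
                              replicates = replicates, seed = seed)
  class(out) <- c("se_titration", class(out))
  out
}

# Mean titration curve: E0 minus the sum of hyperbolic binding events.
titration_mean <- function(conc, e0, amplitudes, s_values) {
  e <- rep(e0, length(conc))
  for (i in seq_along(s_values)) {
    e <- e - amplitudes[i] * conc / (s_values[i] + conc)
  }
  e
}
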