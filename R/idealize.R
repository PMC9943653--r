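#' Idealize a FRET trace with a two-state hidden Markov model
#'
#' Fits a two-state Gaussian-emission HMM by maximum-likelihood EM
#' (Baum-Welch) and labels every frame by the most probable path (Viterbi)
#' under the fitted parameters.  This is the step-function idealization
#' used to harvest dwell times; a maximum-likelihood fit is sufficient for
#' that purpose, so no Bayesian machinery is used.  States are
#' canonically ordered by fitted mean so `high` always denotes the larger
#' (wrapped) efficiency level.  The trace is analysed as exactly two
#' states: possible low-FRET substructure is deliberately collapsed into a
#' single low state.
#'
#' Initialization: means at the 10th/90th percentiles of the trace, both
#' sds at the trace sd, self-transition probability 0.95; up to 3 restarts
#' from jittered initial values if EM degenerates, then a threshold
#' fallback with a warning flag.  Constant-level traces short-circuit to a
#' single-state result with the `degenerate` flag set.
#'
#' @param trace A tibble with columns `time_s` and `fret_e` (>= 20
#'   frames), e.g. one trace of a [simulate_experiment()] cohort.
#' @param init Optional list with entries `means` (length 2), `sds`
#'   (length 2), `trans_prob` (off-diagonal transition probability).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @return A tibble of class `se_idealized` with columns `frame`,
#'   `time_s`, `fret_e`, `label` (`"high"`/`"low"`), and attributes
#'   `means` (named high/low), `sds`, `trans`, `loglik` (per-iteration
#'   trace), `n_transitions`, `degenerate`, `fallback`, `method`.
#' @export
idealize_hmm <- function(trace, init = NULL, tol = 1e-6, max_iter = 500) {
  y <- trace$fret_e
  if (length(y) < 20) abort("trace must have at least 20 frames")
  rng <- range(y)
  sdy <- sd(y)
  if (sdy < 1e-12 || diff(rng) < 1e-12) {
    return(new_idealized(trace, rep("high", length(y)),
                         means = c(high = mean(y), low = mean(y)),
                         sds = c(sdy, sdy), trans = diag(2), loglik = NA_real_,
                         degenerate = TRUE, fallback = FALSE, method = "hmm"))
  }
  if (is.null(init)) {
    q <- quantile(y, c(0.9, 0.1), names = FALSE)
    init <- list(means = q, sds = c(sdy, sdy), trans_prob = 0.05)
  }
  fit <- NULL
  for (attempt in 0:3) {
    mu0 <- init$means
    sd0 <- pmax(init$sds, 1e-4)
    if (attempt > 0) {
      mu0 <- mu0 + rnorm(2, 0, 0.25 * diff(rng))
      sd0 <- sd0 * runif(2, 0.5, 2)
    }
    p <- init$trans_prob
    A0 <- matrix(c(1 - p, p, p, 1 - p), 2, 2)
    cand <- hmm_em_cpp(y, mu0, sd0, A0, c(0.5, 0.5), tol, max_iter,
                       sd_floor = 1e-4 * max(1, diff(rng)))
    if (!cand$degenerate && length(unique(cand$path)) == 2) {
      fit <- cand
      break
    }
    if (is.null(fit) && !cand$degenerate) fit <- cand
  }
  if (is.null(fit)) {
    warn("HMM idealization degenerated; falling back to threshold idealizer.")
    out <- idealize_threshold(trace, cutoff = mean(rng))
    attr(out, "fallback") <- TRUE
    attr(out, "method") <- "hmm"
    return(out)
  }
  hi <- which.max(fit$mu)
  labels <- ifelse(fit$path == hi, "high", "low")
  means <- c(high = fit$mu[hi], low = fit$mu[3 - hi])
  sds <- c(high = fit$sd[hi], low = fit$sd[3 - hi])
  ord <- c(hi, 3 - hi)
  new_idealized(trace, labels, means = means, sds = sds,
                trans = fit$trans[ord, ord], loglik = fit$loglik,
                degenerate = length(unique(labels)) < 2,
                fallback = FALSE, method = "hmm")
}

#' Idealize a FRET trace by thresholding
#'
#' Labels each frame `high` iff its efficiency exceeds `cutoff`.  An
#' optional minimum-dwell filter removes single-frame blips (a one-frame
#' excursion is reassigned to its flanking state, removing two
#' transitions).  Serves as a cross-check on the HMM idealizer and as its
#' degenerate-case fallback.
#'
#' @param trace A tibble with columns `time_s`, `fret_e`.
#' @param cutoff Efficiency threshold, strictly between the observed
#'   minimum and maximum.
#' @param min_dwell_filter If TRUE, remove single-frame dwells.
#' @return An `se_idealized` tibble (see [idealize_hmm()]).
#' @export
idealize_threshold <- function(trace, cutoff, min_dwell_filter = FALSE) {
  y <- trace$fret_e
  if (!(cutoff > min(y) && cutoff < max(y))) {
    abort("`cutoff` must lie strictly within the observed efficiency range.")
  }
  labels <- ifelse(y > cutoff, "high", "low")
  if (min_dwell_filter) {
    r <- rle(labels)
    n <- length(r$lengths)
    for (i in seq_len(n)) {
      if (r$lengths[i] == 1 && n > 1) {
        r$values[i] <- if (i == 1) r$values[2] else r$values[i - 1]
      }
    }
    labels <- inverse.rle(r)
  }
  means <- c(high = mean(y[labels == "high"]), low = mean(y[labels == "low"]))
  sds <- c(high = sd(y[labels == "high"]), low = sd(y[labels == "low"]))
  new_idealized(trace, labels, means = means, sds = sds, trans = NULL,
                loglik = NA_real_, degenerate = length(unique(labels)) < 2,
                fallback = FALSE, method = "threshold")
}

new_idealized <- function(trace, labels, means, sds, trans, loglik,
                          degenerate, fallback, method) {
  out <- tibble(
    frame = if ("frame" %in% names(trace)) trace$frame else seq_along(labels),
    time_s = trace$time_s,
    fret_e = trace$fret_e,
    label = labels
  )
  attr(out, "means") <- means
  attr(out, "sds") <- sds
  attr(out, "trans") <- trans
  attr(out, "loglik") <- loglik
  attr(out, "n_transitions") <- sum(labels[-1] != labels[-length(labels)])
  attr(out, "degenerate") <- degenerate
  attr(out, "fallback") <- fallback
  attr(out, "method") <- method
  attr(out, "conc") <- attr(trace, "conc")
  attr(out, "trace_id") <- attr(trace, "trace_id")
  class(out) <- c("se_idealized", class(out))
  out
}

#' Truncation index for a trace
#'
#' Returns the number of frames to retain.  With bleach detection on, the
#' trace is truncated at the first frame of a sustained (>= 10-frame) run
#' below `e_low - 3 * noise_sd`, the signature of acceptor photobleaching;
#' otherwise the full length capped at `max_duration` is kept.
#'
#' @param trace A tibble with columns `time_s`, `fret_e`.
#' @param bleach_detection Detect and cut at photobleaching?
#' @param max_duration Cap on retained duration (s).
#' @param emission An [emission_model()] row supplying `e_low` and
#'   `noise_sd` for the bleach threshold.
#' @return Integer index (frames retained).
#' @export
truncate_trace <- function(trace, bleach_detection = FALSE,
                           max_duration = Inf,
                           emission = emission_model()) {
  n <- nrow(trace)
  ft <- if (n > 1) trace$time_s[2] - trace$time_s[1] else 1
  idx <- min(n, floor(max_duration / ft))
  if (bleach_detection) {
    thr <- emission$e_low - 3 * emission$noise_sd
    below <- trace$fret_e < thr
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= 10)
    if (length(hit) > 0) idx <- min(idx, starts[hit[1]] - 1L)
  }
  as.integer(max(idx, 0L))
}

#' Idealize every trace of a cohort
#'
#' Maps [idealize_hmm()] (or [idealize_threshold()]) over the traces of a
#' tidy cohort table and returns one tidy label table.
#'
#' @param cohort Tibble with columns `trace_id`, `conc_nM`, `frame`,
#'   `time_s`, `fret_e`.
#' @param method `"hmm"` or `"threshold"`.
#' @param cutoff Threshold cutoff when `method = "threshold"`; default is
#'   the midpoint of the cohort's efficiency 10th/90th percentiles.
#' @param ... Passed to the per-trace idealizer.
#' @return Tibble with columns `trace_id`, `conc_nM`, `frame`, `time_s`,
#'   `fret_e`, `label` plus a `frame_time` attribute.
#' @export
idealize_cohort <- function(cohort, method = c("hmm", "threshold"),
                            cutoff = NULL, ...) {
  method <- match.arg(method)
  if (method == "threshold" && is.null(cutoff)) {
    q <- quantile(cohort$fret_e, c(0.1, 0.9), names = FALSE)
    cutoff <- mean(q)
  }
  ft <- infer_frame_time(cohort)
  out <- cohort |>
    dplyr::group_by(.data$trace_id, .data$conc_nM) |>
    dplyr::group_modify(function(df, key) {
      ideal <- if (method == "hmm") {
        idealize_hmm(df, ...)
      } else {
        idealize_threshold(df, cutoff = cutoff, ...)
      }
      tibble(frame = ideal$frame, time_s = ideal$time_s,
             fret_e = ideal$fret_e, label = ideal$label)
    }) |>
    dplyr::ungroup()
  attr(out, "frame_time") <- ft
  out
}

infer_frame_time <- function(cohort) {
  t2 <- cohort$time_s[cohort$frame == 2]
  t1 <- cohort$time_s[cohort$frame == 1]
  if (length(t2) > 0 && length(t1) > 0) t2[1] - t1[1] else NA_real_
}
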