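#' Convert corrected acceptor ratio to FRET efficiency
#'
#' Minimal affine conversion from an ensemble acceptor-ratio readout to
#' FRET efficiency: `efficiency = (ratioA - d) * f`, where `d` is the
#' direct-excitation offset and `f` the extinction-coefficient scale.
#' With `d = 0, f = 1` this is the identity; values outside `[0, 1]` are
#' passed through (the fit tolerates them) but flagged with a warning.
#'
#' @param ratioA Acceptor ratio value(s).
#' @param direct_excitation_offset Offset `d` subtracted before scaling.
#' @param extinction_scale Scale `f` (> 0).
#' @return Efficiency values, same length as `ratioA`.
#' @export
ratioA_to_efficiency <- function(ratioA, direct_excitation_offset = 0,
                                 extinction_scale = 1) {
  check_pos(extinction_scale, "extinction_scale")
  e <- (ratioA - direct_excitation_offset) * extinction_scale
  if (any(e < 0 | e > 1, na.rm = TRUE)) {
    warn("some converted efficiencies fall outside [0, 1]")
  }
  e
}

#' Fit a binding isotherm (one or two events) to a titration
#'
#' Nonlinear least squares of
#' `E(c) = E0 - sum_i dE_i * c / (S_i + c)` with one (`n_events = 1`) or
#' two (`n_events = 2`) hyperbolic binding events (Hill coefficient fixed
#' at 1).  Replicates are fitted jointly so the standard errors reflect
#' replicate scatter.  Multiple log-spaced initialisations of the
#' half-saturation values are tried and the best residual sum of squares
#' kept; for two events the `S` values are canonically ordered
#' `S1 < S2`.
#'
#' @param curve A titration tibble with columns `conc_nM`, `fret_e`
#'   (replicate column optional), e.g. from [generate_titration()].
#' @param n_events 1 or 2 binding events.
#' @return An object of class `se_isotherm_fit`: list with `params`
#'   (tibble: term, estimate, se), `n_events`, `rss`, `df_residual`,
#'   `n`, `fitted_fn` (function of concentration), `curve`.
#' @export
fit_isotherm <- function(curve, n_events = 1) {
  stopifnot(n_events %in% 1:2)
  nconc <- length(unique(curve$conc_nM))
  if (nconc < 2 * (1 + 2 * n_events)) {
    abort(sprintf("need at least %d distinct concentrations for %d event(s)",
                  2 * (1 + 2 * n_events), n_events))
  }
  dat <- tibble(conc = curve$conc_nM, e = curve$fret_e)
  e0_start <- mean(dat$e[dat$conc == min(dat$conc)])
  amp_tot <- e0_start - mean(dat$e[dat$conc == max(dat$conc)])
  pos <- dat$conc[dat$conc > 0]
  s_grid <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = 6)

  best <- NULL
  if (n_events == 1) {
    fml <- e ~ e0 - dE1 * conc / (S1 + conc)
    starts <- purrr::map(s_grid, function(s) {
      list(e0 = e0_start, dE1 = max(amp_tot, 0.05), S1 = s)
    })
  } else {
    fml <- e ~ e0 - dE1 * conc / (S1 + conc) - dE2 * conc / (S2 + conc)
    combos <- expand.grid(i = seq_along(s_grid), j = seq_along(s_grid))
    combos <- combos[combos$i < combos$j, ]
    starts <- purrr::pmap(combos, function(i, j) {
      list(e0 = e0_start, dE1 = max(amp_tot / 2, 0.02),
           dE2 = max(amp_tot / 2, 0.02), S1 = s_grid[i], S2 = s_grid[j])
    })
  }
  lower <- if (n_events == 1) {
    c(e0 = -Inf, dE1 = 0, S1 = 1e-6)
  } else {
    c(e0 = -Inf, dE1 = 0, dE2 = 0, S1 = 1e-6, S2 = 1e-6)
  }
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = st,
                        lower = unname(lower[names(st)]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) abort("isotherm fit failed to converge from all starts")

  cf <- coef(best$fit)
  sef <- sqrt(diag(vcov(best$fit)))
  if (n_events == 2 && cf["S1"] > cf["S2"]) {
    swap <- function(v) {
      v[c("S1", "S2")] <- v[c("S2", "S1")]
      v[c("dE1", "dE2")] <- v[c("dE2", "dE1")]
      v
    }
    cf <- swap(cf); sef <- swap(sef)
  }
  amps <- unname(cf[grepl("^dE", names(cf))])
  svals <- unname(cf[grepl("^S", names(cf))])
  fitted_fn <- function(conc) titration_mean(conc, cf[["e0"]], amps, svals)
  out <- list(
    params = tibble(term = names(cf), estimate = unname(cf),
                    se = unname(sef)),
    n_events = as.integer(n_events),
    rss = best$rss,
    df_residual = nrow(dat) - length(cf),
    n = nrow(dat),
    fitted_fn = fitted_fn,
    curve = curve
  )
  class(out) <- "se_isotherm_fit"
  out
}

#' Choose between one- and two-event isotherm models
#'
#' Extra-sum-of-squares F-test: quantifies the visual judgement that a
#' titration has one or two inflection points.  Ties (no reduction in
#' residual sum of squares) go to the simpler one-event model.
#'
#' @param fit1,fit2 One- and two-event [fit_isotherm()] fits of the same
#'   curve.
#' @param alpha Test level (default 0.05).
#' @return The chosen `se_isotherm_fit` with a `decision` attribute
#'   (tibble: F statistic, p-value, chosen).
#' @export
select_isotherm_model <- function(fit1, fit2, alpha = 0.05) {
  if (fit1$n_events != 1 || fit2$n_events != 2 || fit1$n != fit2$n) {
    abort("`fit1`/`fit2` must be 1- and 2-event fits of the same curve.")
  }
  df1 <- fit1$df_residual; df2 <- fit2$df_residual
  fstat <- ((fit1$rss - fit2$rss) / (df1 - df2)) / (fit2$rss / df2)
  p <- if (fstat > 0) pf(fstat, df1 - df2, df2, lower.tail = FALSE) else 1
  choose2 <- fit1$rss > fit2$rss && p < alpha
  chosen <- if (choose2) fit2 else fit1
  attr(chosen, "decision") <- tibble(
    f_statistic = fstat, p_value = p, alpha = alpha,
    chosen = chosen$n_events
  )
  chosen
}

#' @export
print.se_isotherm_fit <- function(x, ...) {
  cat(sprintf("Binding isotherm fit (%d event%s):\n", x$n_events,
              if (x$n_events > 1) "s" else ""))
  print(x$params)
  cat(sprintf("RSS %.4g on %d residual df\n", x$rss, x$df_residual))
  invisible(x)
}

#' @rdname fit_isotherm
#' @param x An `se_isotherm_fit` object.
#' @param ... Unused.
#' @export
tidy.se_isotherm_fit <- function(x, ...) {
  x$params
}

#' @rdname fit_isotherm
#' @export
glance.se_isotherm_fit <- function(x, ...) {
  tibble(n_events = x$n_events, rss = x$rss, df_residual = x$df_residual,
         n = x$n)
}
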