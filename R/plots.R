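#' Plot FRET traces
#'
#' Time series of FRET efficiency for one or a few traces, optionally
#' overlaid with idealized state labels.
#'
#' @param cohort Tidy trace tibble (`trace_id`, `time_s`, `fret_e`, ...).
#' @param ids Trace ids to show (default: first 3).
#' @param idealized Optional matching idealized tibble with `label`.
#' @return A ggplot object.
#' @export
plot_fret_trace <- function(cohort, ids = NULL, idealized = NULL) {
  ids <- ids %||% head(unique(cohort$trace_id), 3)
  df <- dplyr::filter(cohort, .data$trace_id %in% ids)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$fret_e)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trace_id), ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "FRET efficiency")
  if (!is.null(idealized)) {
    idf <- dplyr::filter(idealized, .data$trace_id %in% ids)
    means <- idf |>
      dplyr::group_by(.data$trace_id, .data$label) |>
      dplyr::summarise(m = mean(.data$fret_e), .groups = "drop")
    idf <- dplyr::left_join(idf, means, by = c("trace_id", "label"))
    p <- p + ggplot2::geom_step(data = idf,
                                ggplot2::aes(.data$time_s, .data$m),
                                colour = "red", linewidth = 0.4)
  }
  p
}

#' Plot a transition-rate series with fitted curves
#'
#' Apparent high-to-low (binding-limited) and low-to-high
#' (dissociation-limited) transition rates versus TF concentration with
#' bootstrap error bars; a fitted `se_global_fit` adds the three-state
#' closed-form curves.
#'
#' @param series An `se_rate_series` tibble.
#' @param fit Optional `se_global_fit`.
#' @return A ggplot object.
#' @export
plot_rate_series <- function(series, fit = NULL) {
  long <- dplyr::bind_rows(
    tibble(conc_nM = series$conc_nM, rate = "kHL",
           value = series$kHL, se = series$kHL_se),
    tibble(conc_nM = series$conc_nM, rate = "kLH",
           value = series$kLH, se = series$kLH_se)
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$conc_nM, .data$value,
                                          colour = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[TF] (nM)", y = "apparent rate (s^-1)",
                  colour = NULL) +
    ggplot2::scale_colour_manual(
      values = c(kHL = "#c0392b", kLH = "#2c5aa0"),
      labels = c(kHL = "high → low", kLH = "low → high"))
  if (!is.null(fit)) {
    est <- setNames(fit$params$estimate, fit$params$term)
    grid <- tibble(conc_nM = 10^seq(log10(min(series$conc_nM)),
                                    log10(max(series$conc_nM)),
                                    length.out = 100))
    curves <- dplyr::bind_rows(
      dplyr::mutate(grid, rate = "kHL",
                    value = k_high_to_low(est["k12"], est["kon_eff"],
                                          .data$conc_nM)),
      dplyr::mutate(grid, rate = "kLH",
                    value = k_low_to_high(est["k32"], est["kon_eff"],
                                          est["k12"], .data$conc_nM))
    )
    p <- p + ggplot2::geom_line(data = curves)
  }
  p
}

#' @rdname plot_rate_series
#' @param object An `se_global_fit`.
#' @param ... Unused.
#' @export
autoplot.se_global_fit <- function(object, ...) {
  plot_rate_series(object$series, fit = object)
}

#' Plot an isotherm fit
#'
#' Titration points with the fitted one- or two-event binding isotherm
#' on a log concentration axis.
#'
#' @param object An `se_isotherm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_isotherm_fit <- function(object, ...) {
  curve <- object$curve
  pos <- curve$conc_nM[curve$conc_nM > 0]
  grid <- tibble(conc_nM = 10^seq(log10(min(pos)), log10(max(pos)),
                                  length.out = 200))
  grid$fret_e <- object$fitted_fn(grid$conc_nM)
  ggplot2::ggplot(curve, ggplot2::aes(.data$conc_nM, .data$fret_e)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#c0392b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[TF] (nM)", y = "FRET efficiency")
}

#' Plot an occupancy profile against an unwrapping landscape
#'
#' The calibrated relative binding free energy of TF occupancy at each
#' mapped position overlaid on the unwrapping free-energy landscape.
#'
#' @param comparison An `se_landscape_comparison`.
#' @param table The `se_landscape` table used in the comparison.
#' @return A ggplot object.
#' @export
plot_landscape_comparison <- function(comparison, table) {
  ggplot2::ggplot(table, ggplot2::aes(.data$position_bp, .data$ddg_kBT)) +
    ggplot2::geom_area(fill = "grey80") +
    ggplot2::geom_point(data = comparison$residuals,
                        ggplot2::aes(.data$position_bp, .data$profile_kBT),
                        colour = "#1e8449") +
    ggplot2::geom_line(data = comparison$residuals,
                       ggplot2::aes(.data$position_bp, .data$profile_kBT),
                       colour = "#1e8449") +
    ggplot2::labs(x = "bp into nucleosome", y = expression(Delta * Delta *
                                                             G ~ (k[B] * T)))
}
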