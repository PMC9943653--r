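#' Map a binding-site inner edge onto the unwrapping coordinate
#'
#' A TF bound within a partially unwrapped nucleosome traps the DNA
#' unwrapped a few base pairs beyond the inner edge of its target
#' sequence; the default offset of 3 bp places each construct on the
#' unwrapping free-energy coordinate (bp into the nucleosome).
#'
#' @param inner_edge_bp Inner edge of the binding site, bp into the
#'   nucleosome (>= 1); vectorised.
#' @param offset_bp Extra unwrapped base pairs beyond the inner edge
#'   (default 3).
#' @return Mapped position(s) in bp.
#' @examples
#' map_to_unwrap_coordinate(26)  # 29
#' @export
map_to_unwrap_coordinate <- function(inner_edge_bp, offset_bp = 3) {
  if (any(inner_edge_bp < 1)) abort("`inner_edge_bp` must be >= 1")
  inner_edge_bp + offset_bp
}

#' Relative free-energy profile of TF occupancy
#'
#' Converts half-saturation concentrations (ensemble titrations) or
#' effective dissociation constants `KD_eff = k32 / kon_eff`
#' (single-molecule kinetics) into relative binding free energies:
#' `ddG_i = ln(v_i / v_ref)` in units of kBT, with the reference
#' construct at exactly 0.  Errors are propagated to first order:
#' `d(ddG) = sqrt((dv_i/v_i)^2 + (dv_ref/v_ref)^2)`.
#'
#' @param values Tibble with columns `label`, `inner_bp`, `value`
#'   (S1/2 in nM or KD_eff in nM, > 0) and optionally `se`.
#' @param reference Label of the reference construct (must be present).
#' @param source `"ensemble"` or `"kinetic"` (metadata only).
#' @param offset_bp Passed to [map_to_unwrap_coordinate()].
#' @return A tibble of class `se_energy_profile` with columns `label`,
#'   `inner_bp`, `position_bp`, `ddg_kBT`, `ddg_se` and attributes
#'   `reference`, `source`.
#' @examples
#' vals <- tibble::tibble(label = c("P26", "P31"), inner_bp = c(26, 31),
#'                        value = c(4.3, 500), se = c(0.2, 100))
#' ddg_profile(vals, reference = "P26")
#' @export
ddg_profile <- function(values, reference,
                        source = c("ensemble", "kinetic"), offset_bp = 3) {
  source <- match.arg(source)
  if (!reference %in% values$label) abort("reference label not found")
  check_pos(values$value, "value")
  if (!"se" %in% names(values)) values$se <- 0
  ref <- values[values$label == reference, ]
  out <- values |>
    dplyr::mutate(
      position_bp = map_to_unwrap_coordinate(.data$inner_bp, offset_bp),
      ddg_kBT = log(.data$value / ref$value),
      ddg_se = sqrt((.data$se / .data$value)^2 + (ref$se / ref$value)^2)
    ) |>
    dplyr::mutate(
      # the reference is exactly zero with its own uncertainty undefined
      ddg_kBT = ifelse(.data$label == reference, 0, .data$ddg_kBT),
      ddg_se = ifelse(.data$label == reference, 0, .data$ddg_se)
    ) |>
    dplyr::select("label", "inner_bp", "position_bp", "ddg_kBT", "ddg_se")
  attr(out, "reference") <- reference
  attr(out, "source") <- source
  class(out) <- c("se_energy_profile", class(out))
  out
}

#' Synthetic nucleosome unwrapping free-energy landscape
#'
#' A synthetic stand-in for a published unwrapping free-energy landscape
#' (which is not redistributed here): a shallow, gently rising outer
#' region over the first ~30 bp, a sharp ~5 kBT rise between 30 and
#' 35 bp, and a continued gradual climb beyond.  Useful for exercising
#' [compare_to_landscape()] and for illustrating the two-region
#' accessibility structure; substitute a measured table (via
#' [read_landscape_table()]) for real comparisons.
#'
#' @param bp_range Integer positions covered (default 1:60).
#' @return A tibble of class `se_landscape` with columns `position_bp`,
#'   `ddg_kBT`.
#' @export
synthetic_unwrap_landscape <- function(bp_range = 1:60) {
  bp <- as.numeric(bp_range)
  ddg <- 0.08 * bp +                         # shallow outer slope
    5 / (1 + exp(-(bp - 32.5) / 1.1)) +      # sharp 30-35 bp rise
    0.04 * pmax(bp - 35, 0)                  # gradual climb inside
  out <- tibble(position_bp = bp, ddg_kBT = ddg - ddg[1])
  class(out) <- c("se_landscape", class(out))
  out
}

#' Read / write an unwrapping landscape table
#'
#' Plain TSV with columns `position_bp` (strictly increasing bp into the
#' nucleosome) and `ddg_kBT`.
#'
#' @param path File path.
#' @return A tibble of class `se_landscape`.
#' @export
read_landscape_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("position_bp", "ddg_kBT") %in% names(out))) {
    abort("landscape table needs columns position_bp, ddg_kBT")
  }
  if (any(diff(out$position_bp) <= 0)) {
    abort("position_bp must be strictly increasing")
  }
  class(out) <- c("se_landscape", class(out))
  out
}

#' @rdname read_landscape_table
#' @param table An `se_landscape` tibble.
#' @export
write_landscape_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Compare an occupancy free-energy profile to an unwrapping landscape
#'
#' Calibrates the occupancy profile to the landscape by shifting it by a
#' constant so that its value at the calibration position equals the
#' (linearly interpolated) landscape value there — relative free energies
#' carry an arbitrary offset, so the comparison is translation-invariant.
#' Then compares the calibrated profile values with the landscape values
#' interpolated at the same positions: per-position residuals and a
#' two-sample Kolmogorov-Smirnov test.  A paired sign-flip permutation
#' test on the residuals is offered as an alternative.
#'
#' @param profile An [ddg_profile()] result.
#' @param table An `se_landscape` table covering all mapped positions.
#' @param calibration_bp Calibration position (bp); must be one of the
#'   profile's mapped positions and lie inside the table range.
#' @param method `"ks"` (two-sample Kolmogorov-Smirnov, default) or
#'   `"permutation"` (paired sign-flip test on mean absolute residual,
#'   2^n or 10000 random flips).
#' @return A list of class `se_landscape_comparison`: `offset_applied`,
#'   `residuals` (tibble: label, position_bp, profile_kBT, landscape_kBT,
#'   residual), `statistic`, `p_value`, `method`.
#' @export
compare_to_landscape <- function(profile, table, calibration_bp = 29,
                                 method = c("ks", "permutation")) {
  method <- match.arg(method)
  pos <- profile$position_bp
  if (any(pos < min(table$position_bp) | pos > max(table$position_bp))) {
    abort("profile positions fall outside the landscape table range")
  }
  if (!calibration_bp %in% pos) {
    abort("`calibration_bp` must be one of the profile's mapped positions")
  }
  land_at <- function(p) approx(table$position_bp, table$ddg_kBT, p)$y
  offset <- land_at(calibration_bp) -
    profile$ddg_kBT[match(calibration_bp, pos)]
  cal <- profile$ddg_kBT + offset
  land <- land_at(pos)
  resid <- cal - land
  if (method == "ks") {
    kt <- suppressWarnings(ks.test(cal, land))
    statistic <- unname(kt$statistic)
    p_value <- kt$p.value
  } else {
    n <- length(resid)
    obs <- mean(abs(mean(resid)))
    if (n <= 14) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      signs <- matrix(sample(c(-1, 1), 10000 * n, replace = TRUE),
                      ncol = n)
    }
    null <- abs(signs %*% resid) / n
    statistic <- obs
    p_value <- mean(null >= obs - 1e-12)
  }
  structure(list(
    offset_applied = offset,
    residuals = tibble(label = profile$label, position_bp = pos,
                       profile_kBT = cal, landscape_kBT = land,
                       residual = resid),
    statistic = statistic, p_value = p_value, method = method
  ), class = "se_landscape_comparison")
}

#' @export
print.se_landscape_comparison <- function(x, ...) {
  cat(sprintf("Landscape comparison (%s): statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  cat(sprintf("calibration offset applied: %.4g kBT\n", x$offset_applied))
  print(x$residuals)
  invisible(x)
}

#' Convert kBT to kcal/mol
#'
#' @param kbt Energy in kBT units.
#' @param temperature_K Temperature (default 298 K, where 1 kBT =
#'   0.593 kcal/mol).
#' @return Energy in kcal/mol.
#' @export
kbt_to_kcal <- function(kbt, temperature_K = 298) {
  kbt * 0.593 * temperature_K / 298
}
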