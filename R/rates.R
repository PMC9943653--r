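#' Elementary rate set of the three-state site-exposure model
#'
#' Bundles the four elementary rates of the Polach-Widom site-exposure
#' scheme for a transcription factor (TF) binding a target site inside a
#' nucleosome: state 1 is the wrapped nucleosome (site occluded), state 2
#' the transiently unwrapped nucleosome with the site exposed but unbound,
#' and state 3 the unwrapped nucleosome with the TF bound.
#'
#' The derived effective binding rate constant is
#' `kon_eff = (k12 / k21) * k23`: the site-exposure-limited on-rate that a
#' bulk experiment actually sees.  The closed-form concentration
#' dependences used throughout the package assume the unwrapping rate is
#' small relative to rewrapping (`k12 < k21`); `regime_valid` records
#' whether the supplied rates satisfy that premise.
#'
#' @param k12 Nucleosome unwrapping rate (s^-1).
#' @param k21 Nucleosome rewrapping rate (s^-1).  Not identifiable from
#'   dwell-time fits; the simulation default elsewhere is 100 s^-1,
#'   matching rewrapping on the 10 ms time scale.
#' @param k23 Bimolecular TF binding rate constant to the exposed site
#'   (nM^-1 s^-1).
#' @param k32 TF dissociation rate from the nucleosomal site (s^-1).
#' @return A one-row tibble of class `se_rates` with columns `k12`, `k21`,
#'   `k23`, `k32`, `kon_eff`, `regime_valid`.
#' @examples
#' rate_set(k12 = 2.5, k21 = 100, k23 = 4.4, k32 = 0.66)
#' @export
rate_set <- function(k12, k21, k23, k32) {
  check_nonneg(k12, "k12"); check_nonneg(k21, "k21")
  check_nonneg(k23, "k23"); check_nonneg(k32, "k32")
  out <- tibble(
    k12 = k12, k21 = k21, k23 = k23, k32 = k32,
    kon_eff = if (k21 > 0) k12 * k23 / k21 else NA_real_,
    regime_valid = k12 < k21
  )
  class(out) <- c("se_rates", class(out))
  out
}

#' Identifiable effective parameter triple
#'
#' The global fit of transition rates versus TF concentration identifies
#' only three parameters: the unwrapping rate `k12`, the TF dissociation
#' rate `k32`, and the effective binding rate constant `kon_eff`.  `k21`
#' and `k23` enter only through their ratio.
#'
#' @param k12 Unwrapping rate (s^-1).
#' @param k32 TF dissociation rate (s^-1).
#' @param kon_eff Effective binding rate constant (nM^-1 s^-1).
#' @return A one-row tibble of class `se_params`.
#' @export
effective_params <- function(k12, k32, kon_eff) {
  check_nonneg(k12, "k12"); check_nonneg(k32, "k32")
  check_nonneg(kon_eff, "kon_eff")
  out <- tibble(k12 = k12, k32 = k32, kon_eff = kon_eff)
  class(out) <- c("se_params", class(out))
  out
}

#' Generator matrix of the three-state chain
#'
#' Builds the 3x3 rate (generator) matrix `R` of the master equation
#' `dX/dt = R X`, with columns indexed by the from-state so each column of
#' the full generator sums to zero.  Two absorbing variants reproduce the
#' matrices used to derive the closed-form transition rates: the `binding`
#' variant sets `k32 = 0` (state 3 absorbing; relaxation into the bound
#' state) and the `release` variant sets `k12 = 0` (state 1 absorbing;
#' relaxation back to the wrapped state).  Absorbing states keep their row
#' and column so indices always mean the same physical states.
#'
#' @param rates An [rate_set()] object (or anything with columns
#'   `k12`, `k21`, `k23`, `k32`).
#' @param conc TF concentration in nM (scalar, >= 0).
#' @param variant `"full"`, `"binding"` or `"release"`.
#' @return A 3x3 numeric matrix.
#' @examples
#' r <- rate_set(2.5, 100, 4.4, 0.66)
#' build_rate_matrix(r, conc = 10, variant = "binding")
#' @export
build_rate_matrix <- function(rates, conc,
                              variant = c("full", "binding", "release")) {
  variant <- match.arg(variant)
  check_nonneg(conc, "conc")
  k12 <- rates$k12; k21 <- rates$k21; k23 <- rates$k23; k32 <- rates$k32
  check_nonneg(c(k12, k21, k23, k32), "rates")
  if (variant == "binding") k32 <- 0
  if (variant == "release") k12 <- 0
  kb <- k23 * conc
  matrix(c(
    -k12,        k21,              0,
     k12,       -k21 - kb,        k32,
       0,        kb,             -k32
  ), nrow = 3, byrow = TRUE)
}

#' Closed-form high-to-low FRET transition rate
#'
#' Apparent rate of leaving the high-FRET (fully wrapped) state for the
#' low-FRET (unwrapped, TF-bound) state as a function of TF concentration:
#' `k_HL(c) = k12 / (1 + k12 / (kon_eff * c))`.  Rises linearly as
#' `kon_eff * c` at low concentration and saturates at the unwrapping rate
#' `k12` when binding outpaces rewrapping.
#'
#' @param k12 Unwrapping rate (s^-1).
#' @param kon_eff Effective binding rate constant (nM^-1 s^-1).
#' @param conc TF concentration (nM); vectorised.  `conc = 0` returns the
#'   limit 0.
#' @return Apparent transition rate(s) in s^-1.
#' @export
k_high_to_low <- function(k12, kon_eff, conc) {
  check_nonneg(k12, "k12"); check_nonneg(kon_eff, "kon_eff")
  check_nonneg(conc, "conc")
  ifelse(conc == 0, 0, k12 / (1 + k12 / (kon_eff * conc)))
}

#' Closed-form low-to-high FRET transition rate
#'
#' Apparent rate of returning from the low-FRET (TF-bound) state to the
#' high-FRET (wrapped) state:
#' `k_LH(c) = k32 / (1 + kon_eff * c / k12)`.  Equals the dissociation
#' rate `k32` at zero concentration and decays hyperbolically once the TF
#' rebinds faster than the nucleosome rewraps (the TF exchanges several
#' times per rewrapping event).
#'
#' @inheritParams k_high_to_low
#' @param k32 TF dissociation rate (s^-1).
#' @return Apparent transition rate(s) in s^-1.
#' @export
k_low_to_high <- function(k32, kon_eff, k12, conc) {
  check_nonneg(k32, "k32"); check_nonneg(kon_eff, "kon_eff")
  check_pos(k12, "k12"); check_nonneg(conc, "conc")
  k32 / (1 + kon_eff * conc / k12)
}

#' Propagate the master equation
#'
#' Solves `dX/dt = R X` exactly for the given generator (or absorbing
#' variant) by eigendecomposition, falling back to a scaling-and-squaring
#' matrix exponential when the eigenvector matrix is near-defective.
#'
#' @param matrix 3x3 generator from [build_rate_matrix()].
#' @param x0 Initial state distribution (length-3, sums to 1).
#' @param t Time(s) in seconds (>= 0); vectorised.
#' @return A tibble with columns `t`, `p1`, `p2`, `p3`.
#' @export
propagate_master_equation <- function(matrix, x0, t) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
  if (length(x0) != 3 || any(x0 < -1e-12) || abs(sum(x0) - 1) > 1e-9) {
    abort("`x0` must be a probability vector over the 3 states.")
  }
  cs <- colSums(matrix)
  absorbing <- which(apply(matrix, 2, function(x) all(x == 0)))
  if (any(abs(cs) > 1e-8)) {
    abort("`matrix` is not a generator: columns must sum to 0.")
  }
  check_nonneg(t, "t")
  sol <- spectral_solution(matrix, x0 = x0)
  if (!sol$defective) {
    lam <- sol$eigenvalues
    C <- sol$coefficients        # 3 x 3, one column per mode
    pt <- vapply(t, function(tt) {
      Re(C %*% exp(lam * tt))
    }, numeric(3))
  } else {
    pt <- vapply(t, function(tt) expm_ss(matrix * tt) %*% x0, numeric(3))
  }
  pt <- pmin(pmax(pt, 0), 1)
  tibble(t = t, p1 = pt[1, ], p2 = pt[2, ], p3 = pt[3, ])
}

#' Spectral solution of the master equation
#'
#' Eigendecomposition of the generator: the relaxation of the state
#' distribution is `X(t) = C0 exp(l0 t) + C- exp(l- t) + C+ exp(l+ t)`
#' where `l0 = 0` and `l-` <= `l+` < 0 are the eigenvalues and the
#' coefficient vectors `Ci` depend on the initial distribution.  Under the
#' site-exposure regime (`k12 << k21`, `k12 << k23*c`) the slow eigenvalue
#' `l+` of the binding variant equals minus the closed-form
#' [k_high_to_low()] rate.
#'
#' @param matrix 3x3 generator or absorbing variant.
#' @param x0 Initial distribution used to form the coefficient vectors;
#'   defaults to starting fully wrapped (`c(1, 0, 0)`), the natural
#'   initial condition when unwrapping is rare.
#' @return A list of class `se_spectral` with `eigenvalues` (sorted
#'   ascending in real part: `l-`, `l+`, `l0`-last = 0), `coefficients`
#'   (3x3 matrix, one column per mode, same order), and `defective`
#'   (TRUE when the eigendecomposition was numerically unreliable and a
#'   matrix-exponential fallback should be used for propagation).
#' @export
spectral_solution <- function(matrix, x0 = c(1, 0, 0)) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
  eg <- eigen(matrix)
  lam <- eg$values
  V <- eg$vectors
  ord <- order(Re(lam))        # l- , l+ , l0
  lam <- lam[ord]; V <- V[, ord, drop = FALSE]
  # snap the conserved mode to exactly zero
  i0 <- which.min(abs(lam))
  if (abs(lam[i0]) < 1e-10) lam[i0] <- 0
  defective <- abs(det(V)) < 1e-10 ||
    min(abs(diff(sort(Re(lam))))) < 1e-12 * max(1, max(abs(lam)))
  coefs <- NULL
  if (!defective) {
    w <- solve(V, x0)
    coefs <- V %*% diag(as.complex(w), 3)
    if (max(abs(Im(coefs))) < 1e-8) coefs <- Re(coefs)
  }
  structure(list(eigenvalues = lam, coefficients = coefs,
                 defective = defective),
            class = "se_spectral")
}

# Scaling-and-squaring matrix exponential (Pade-free Taylor variant is
# sufficient at 3x3 with squaring); tolerance ~1e-10.
expm_ss <- function(M) {
  nrm <- max(abs(M))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 4L)
  A <- M / 2^j
  E <- diag(3)
  term <- diag(3)
  for (k in 1:20) {
    term <- term %*% A / k
    E <- E + term
    if (max(abs(term)) < 1e-16) break
  }
  for (i in seq_len(j)) E <- E %*% E
  E
}

#' Regime metrics of an effective parameter triple
#'
#' Two characteristic concentrations classify where on the nucleosome a
#' binding site sits kinetically.  `KD_eff = k32 / kon_eff` is the
#' effective dissociation constant of TF occupancy (the concentration at
#' which the site is half occupied).  `c_cross = k12 / kon_eff`, which
#' equals `k21 / k23`, is the concentration at which TF binding to the
#' exposed site outpaces nucleosome rewrapping.  Their ratio
#' `regime_ratio = KD_eff / c_cross = k32 / k12` is << 1 for outer-region
#' sites (occupancy saturates before binding outruns rewrapping) and ~1
#' for inner-region sites.
#'
#' @param params An [effective_params()] row (k12, k32, kon_eff).
#' @return A one-row tibble with `KD_eff` (nM), `c_cross` (nM),
#'   `regime_ratio`.
#' @examples
#' regime_metrics(effective_params(k12 = 2.5, k32 = 0.66, kon_eff = 0.11))
#' @export
regime_metrics <- function(params) {
  check_pos(params$kon_eff, "kon_eff")
  check_pos(params$k12, "k12")
  tibble(
    KD_eff = params$k32 / params$kon_eff,
    c_cross = params$k12 / params$kon_eff,
    regime_ratio = params$k32 / params$k12
  )
}
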