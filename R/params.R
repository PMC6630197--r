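#' Amphoteric surface parameters
#'
#' Container for the six quantities of the two-group acid-base tension model
#' of a phospholipid bilayer: the four component interfacial tensions of the
#' headgroup species (deprotonated phosphate `X-`, protonated phosphate `XH`,
#' protonated amine `Y+`, hydroxide-associated amine `YOH`) and the two
#' association constants.
#'
#' `K_X` and `K_Y` are *association* constants (`K = 10^pK`, units 1/M): `K_X`
#' for proton binding to the phosphate group and `K_Y` for hydroxide binding
#' to the ammonium group. They are **not** conventional acid-dissociation
#' `Ka`; the pK exponents printed for DPPC/DPPE (2.58/5.69 and 2.42/5.98)
#' are exponents of these association constants.
#'
#' @param gamma_Xminus0 Component tension of the deprotonated phosphate
#'   species, N/m (>= 0).
#' @param gamma_XH0 Component tension of the protonated phosphate species,
#'   N/m (>= 0).
#' @param gamma_Yplus0 Component tension of the protonated amine species,
#'   N/m (>= 0).
#' @param gamma_YOH0 Component tension of the hydroxide-associated amine
#'   species, N/m (>= 0).
#' @param K_X Phosphate-proton association constant, 1/M (> 0).
#' @param K_Y Amine-hydroxide association constant, 1/M (> 0).
#' @return An object of class `amphoteric_params`.
#' @seealso [identifiable_params()], [gamma_of_pH()]
#' @export
#' @examples
#' p <- amphoteric_params(2.3e-3, 1.1e-3, 1.2e-3, 0.2e-3,
#'                        K_X = 10^2.58, K_Y = 10^5.69)
#' gamma_of_pH(p, 4.14)
amphoteric_params <- function(gamma_Xminus0, gamma_XH0, gamma_Yplus0,
                              gamma_YOH0, K_X, K_Y) {
  vals <- c(gamma_Xminus0 = gamma_Xminus0, gamma_XH0 = gamma_XH0,
            gamma_Yplus0 = gamma_Yplus0, gamma_YOH0 = gamma_YOH0,
            K_X = K_X, K_Y = K_Y)
  if (!all(is.finite(vals)))
    stop("amphoteric_params: all fields must be finite numbers")
  if (any(vals[1:4] < 0))
    stop("amphoteric_params: component tensions must be >= 0")
  if (K_X <= 0 || K_Y <= 0)
    stop("amphoteric_params: association constants must be > 0")
  structure(as.list(vals), class = "amphoteric_params")
}

#' @export
print.amphoteric_params <- function(x, ...) {
  cat("Amphoteric surface parameters (two-group acid-base model)\n")
  cat(sprintf("  gamma0 [N/m]: X- %.4g  XH %.4g  Y+ %.4g  YOH %.4g\n",
              x$gamma_Xminus0, x$gamma_XH0, x$gamma_Yplus0, x$gamma_YOH0))
  cat(sprintf("  pK_X %.3f  pK_Y %.3f (association constants, K = 10^pK)\n",
              log10(x$K_X), log10(x$K_Y)))
  invisible(x)
}

#' Identifiable reparameterization of the tension model
#'
#' The two-sigmoid tension model only determines the baseline sum
#' `B = gamma_Xminus0 + gamma_Yplus0`, the two amplitudes
#' `A_X = gamma_XH0 - gamma_Xminus0` and `A_Y = gamma_YOH0 - gamma_Yplus0`,
#' and the two pK exponents; the split of `B` into its two addends is not
#' recoverable from tension-versus-pH data. Fitting is therefore done in this
#' five-parameter form.
#'
#' @param baseline_B Baseline tension `gamma_Xminus0 + gamma_Yplus0`, N/m.
#' @param amp_AX Low-pH amplitude `gamma_XH0 - gamma_Xminus0`, N/m.
#' @param amp_AY High-pH amplitude `gamma_YOH0 - gamma_Yplus0`, N/m.
#' @param log10_K_X Exponent of the phosphate-proton association constant.
#' @param log10_K_Y Exponent of the amine-hydroxide association constant.
#' @return An object of class `identifiable_params`.
#' @seealso [as_identifiable()], [as_amphoteric()]
#' @export
identifiable_params <- function(baseline_B, amp_AX, amp_AY,
                                log10_K_X, log10_K_Y) {
  vals <- c(baseline_B = baseline_B, amp_AX = amp_AX, amp_AY = amp_AY,
            log10_K_X = log10_K_X, log10_K_Y = log10_K_Y)
  if (!all(is.finite(vals)))
    stop("identifiable_params: all fields must be finite numbers")
  structure(as.list(vals), class = "identifiable_params")
}

#' @export
print.identifiable_params <- function(x, ...) {
  cat("Identifiable tension-model parameters\n")
  cat(sprintf("  baseline B %.6g N/m, amplitudes A_X %.6g, A_Y %.6g N/m\n",
              x$baseline_B, x$amp_AX, x$amp_AY))
  cat(sprintf("  pK_X %.4f  pK_Y %.4f\n", x$log10_K_X, x$log10_K_Y))
  invisible(x)
}

#' Convert full parameters to the identifiable form
#'
#' @param params An `amphoteric_params` object.
#' @return An `identifiable_params` object describing the same tension curve.
#' @export
as_identifiable <- function(params) {
  stopifnot(inherits(params, "amphoteric_params"))
  identifiable_params(
    baseline_B = params$gamma_Xminus0 + params$gamma_Yplus0,
    amp_AX = params$gamma_XH0 - params$gamma_Xminus0,
    amp_AY = params$gamma_YOH0 - params$gamma_Yplus0,
    log10_K_X = log10(params$K_X),
    log10_K_Y = log10(params$K_Y))
}

#' Reconstruct full parameters from the identifiable form
#'
#' The split of the baseline `B` into `gamma_Xminus0 + gamma_Yplus0` is not
#' identifiable; any split that keeps all four component tensions
#' non-negative reproduces the same tension curve. By default the midpoint of
#' the feasible interval for `gamma_Yplus0` is used.
#'
#' @param ip An `identifiable_params` object.
#' @param gamma_Yplus0 Optional explicit value for the `Y+` component tension
#'   (the `X-` component is then `B - gamma_Yplus0`).
#' @return An `amphoteric_params` object.
#' @export
as_amphoteric <- function(ip, gamma_Yplus0 = NULL) {
  stopifnot(inherits(ip, "identifiable_params"))
  lo <- max(0, -ip$amp_AY)                   # need gamma_YOH0 >= 0
  hi <- min(ip$baseline_B, ip$baseline_B + ip$amp_AX)  # need gamma_XH0 >= 0
  if (is.null(gamma_Yplus0)) {
    if (lo > hi)
      stop("as_amphoteric: no non-negative split of the baseline exists")
    gamma_Yplus0 <- (lo + hi) / 2
  }
  amphoteric_params(
    gamma_Xminus0 = ip$baseline_B - gamma_Yplus0,
    gamma_XH0 = ip$baseline_B - gamma_Yplus0 + ip$amp_AX,
    gamma_Yplus0 = gamma_Yplus0,
    gamma_YOH0 = gamma_Yplus0 + ip$amp_AY,
    K_X = 10^ip$log10_K_X, K_Y = 10^ip$log10_K_Y)
}

#' Proton and hydroxide activities at a given pH
#'
#' Ideal-solution convention: `a_H = 10^(-pH)`, `a_OH = 10^(pH - pKw)`, so
#' that `a_H * a_OH = 10^(-pKw)` exactly.
#'
#' @param pH Solution pH (finite, vectorized).
#' @param pKw Ion-product exponent of water (default 14.0; no temperature
#'   correction is applied).
#' @return A list with components `a_H`, `a_OH` (mol/L) and `pKw`.
#' @export
ion_activities <- function(pH, pKw = 14.0) {
  if (!all(is.finite(pH))) stop("ion_activities: pH must be finite")
  if (!is.finite(pKw)) stop("ion_activities: pKw must be finite")
  list(a_H = 10^(-pH), a_OH = 10^(pH - pKw), pKw = pKw)
}
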