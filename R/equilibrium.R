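#' Interfacial tension of an amphoteric bilayer at a given pH
#'
#' Evaluates the four-term acid-base tension model: each headgroup equilibrium
#' (proton binding to phosphate, hydroxide binding to the ammonium group)
#' mixes the component tensions of its two species with sigmoid weights in
#' `a_H` and `a_OH` respectively,
#' \deqn{\gamma = \frac{\gamma^0_{X^-}}{1 + K_X a_{H^+}}
#'             + \frac{\gamma^0_{XH} K_X a_{H^+}}{1 + K_X a_{H^+}}
#'             + \frac{\gamma^0_{Y^+}}{1 + K_Y a_{OH^-}}
#'             + \frac{\gamma^0_{YOH} K_Y a_{OH^-}}{1 + K_Y a_{OH^-}}.}
#'
#' @param params An [amphoteric_params()] or [identifiable_params()] object.
#' @param pH Solution pH (finite; vectorized).
#' @param pKw Ion-product exponent of water (default 14.0).
#' @return Interfacial tension in N/m, same length as `pH`.
#' @export
#' @examples
#' p <- dppc_params()
#' gamma_of_pH(p, c(2, 4.14, 7.4))
gamma_of_pH <- function(params, pH, pKw = 14.0) {
  if (inherits(params, "identifiable_params")) params <- as_amphoteric(params)
  stopifnot(inherits(params, "amphoteric_params"))
  act <- ion_activities(pH, pKw)
  wX <- params$K_X * act$a_H / (1 + params$K_X * act$a_H)   # fraction XH
  wY <- params$K_Y * act$a_OH / (1 + params$K_Y * act$a_OH) # fraction YOH
  params$gamma_Xminus0 * (1 - wX) + params$gamma_XH0 * wX +
    params$gamma_Yplus0 * (1 - wY) + params$gamma_YOH0 * wY
}

#' Headgroup speciation fractions at a given pH
#'
#' @inheritParams gamma_of_pH
#' @return A data frame with columns `pH`, `f_XH`, `f_Xminus`, `f_Yplus`,
#'   `f_YOH`. Complementary pairs sum to 1 exactly:
#'   `f_XH + f_Xminus == 1` and `f_Yplus + f_YOH == 1`.
#' @export
speciation_fractions <- function(params, pH, pKw = 14.0) {
  if (inherits(params, "identifiable_params")) params <- as_amphoteric(params)
  stopifnot(inherits(params, "amphoteric_params"))
  act <- ion_activities(pH, pKw)
  f_XH <- params$K_X * act$a_H / (1 + params$K_X * act$a_H)
  f_YOH <- params$K_Y * act$a_OH / (1 + params$K_Y * act$a_OH)
  data.frame(pH = pH, f_XH = f_XH, f_Xminus = 1 - f_XH,
             f_Yplus = 1 - f_YOH, f_YOH = f_YOH)
}

#' Limiting plateau tensions of the model
#'
#' At strongly acidic pH the phosphate is fully protonated and the amine
#' fully cationic (`gamma_XH0 + gamma_Yplus0`); at strongly basic pH the
#' phosphate is deprotonated and the amine hydroxide-associated
#' (`gamma_Xminus0 + gamma_YOH0`).
#'
#' @param params An [amphoteric_params()] or [identifiable_params()] object.
#' @return Named numeric vector `c(gamma_lowpH, gamma_highpH)` in N/m.
#' @export
limiting_tensions <- function(params) {
  if (inherits(params, "identifiable_params")) params <- as_amphoteric(params)
  stopifnot(inherits(params, "amphoteric_params"))
  c(gamma_lowpH = params$gamma_XH0 + params$gamma_Yplus0,
    gamma_highpH = params$gamma_Xminus0 + params$gamma_YOH0)
}

#' Isoelectric point from the two association-constant exponents
#'
#' The default (`method = "mean"`) is the arithmetic mean
#' `(pK_X + pK_Y) / 2`, which reproduces the reference values for DPPC
#' (2.58, 5.69 -> 4.14) and DPPE (2.42, 5.98 -> 4.20) exactly. A naive
#' charge-balance condition (equal concentrations of the anionic phosphate
#' and cationic amine species) instead gives `(pKw + pK_X - pK_Y) / 2`,
#' available as `method = "charge_balance"`; for DPPC it yields 5.45, which
#' is inconsistent with the tabulated pI, so the mean rule is normative.
#'
#' @param pK_X Exponent of the phosphate-proton association constant.
#' @param pK_Y Exponent of the amine-hydroxide association constant.
#' @param method `"mean"` (default) or `"charge_balance"`.
#' @param pKw Ion-product exponent, used only by `"charge_balance"`.
#' @return The isoelectric pH (unrounded; round for display).
#' @export
#' @examples
#' round(compute_pI(2.58, 5.69), 2)  # 4.14 (DPPC)
#' round(compute_pI(2.42, 5.98), 2)  # 4.20 (DPPE)
compute_pI <- function(pK_X, pK_Y, method = c("mean", "charge_balance"),
                       pKw = 14.0) {
  if (!all(is.finite(c(pK_X, pK_Y))))
    stop("compute_pI: pK exponents must be finite")
  method <- match.arg(method)
  switch(method,
         mean = (pK_X + pK_Y) / 2,
         charge_balance = (pKw + pK_X - pK_Y) / 2)
}

#' Display rounding with ties away from zero
#'
#' Decimal "half-up" rounding as used when reporting values like pI to a
#' fixed number of places: 4.135 becomes 4.14. (Both `base::round()` and
#' binary floating point would give 4.13 here, because 4.135 is stored as
#' 4.13499...; scientific tables round the decimal value up.)
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(compute_pI(2.58, 5.69), 2)  # 4.14
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
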