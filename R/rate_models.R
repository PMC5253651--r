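#' @title Rate laws and binding thermodynamics
#' @name rate_models
#' @description Closed-form steady-state rate laws (competitive product
#'   inhibition and its Michaelis-Menten reduction, with an optional
#'   substrate-inhibition extension used only by the simulator) and the
#'   standard Kd -> deltaG -> TdeltaS conversions used to tabulate ITC
#'   binding thermodynamics.
NULL

# gas constant in kcal mol^-1 K^-1; all energies in the package are kcal/mol
.R_KCAL <- 1.98720e-3

#' Kinetic parameter set for the product-inhibition rate law
#'
#' Bundles Vmax, Km and the product-affinity term Kp of the steady-state
#' rate law \eqn{v = Vmax \cdot S / (Km (1 + P/Kp) + S)}, optionally with a
#' substrate-inhibition constant Ksi (simulation-only extension) and the
#' molar reaction enthalpy used to translate rates into thermal power.
#' Internal units are mol/L and seconds throughout; the `*_uM` convenience
#' arguments accept micromolar values.
#'
#' @param Vmax maximal rate (mol L^-1 s^-1). Alternatively supply `kcat`
#'   and `enzyme`.
#' @param Km Michaelis constant (mol/L), must be positive.
#' @param Kp product affinity term (mol/L), must be positive. Use `Inf`
#'   for no product inhibition.
#' @param kcat turnover number (s^-1); if both `kcat` and `Vmax` are given
#'   together with `enzyme` they must agree to 1 part in 1e6.
#' @param enzyme enzyme concentration (mol/L, monomers).
#' @param dH_rxn molar reaction enthalpy (kcal/mol), negative for
#'   exothermic reactions.
#' @param Ksi optional substrate-inhibition constant (mol/L); `NULL`
#'   (default) disables the substrate-inhibition term.
#' @return an object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params(kcat = 0.90, enzyme = 450e-9, Km = 1.1e-6, Kp = 6e-6,
#'                      dH_rxn = -22.5)
#' rate_product_inhibition(10e-6, 14e-6, kp)
#' @export
kinetic_params <- function(Vmax = NULL, Km, Kp = Inf, kcat = NULL,
                           enzyme = NULL, dH_rxn = NA_real_, Ksi = NULL) {
  if (is.null(Vmax) && (is.null(kcat) || is.null(enzyme)))
    stop("supply Vmax, or kcat together with enzyme", call. = FALSE)
  if (!is.null(kcat) && !is.null(enzyme)) {
    v_from_kcat <- kcat * enzyme
    if (is.null(Vmax)) {
      Vmax <- v_from_kcat
    } else if (abs(Vmax - v_from_kcat) > 1e-6 * abs(Vmax)) {
      stop("inconsistent Vmax and kcat * enzyme (differ by more than 1e-6 relative)",
           call. = FALSE)
    }
  }
  if (Vmax < 0) stop("Vmax must be non-negative", call. = FALSE)
  if (!(Km > 0)) stop("Km must be positive", call. = FALSE)
  if (!(Kp > 0)) stop("Kp must be positive", call. = FALSE)
  if (!is.null(Ksi) && !(Ksi > 0)) stop("Ksi must be positive when given", call. = FALSE)
  if (is.null(kcat) && !is.null(enzyme)) kcat <- Vmax / enzyme
  structure(list(Vmax = Vmax, Km = Km, Kp = Kp, kcat = kcat,
                 enzyme = enzyme, dH_rxn = dH_rxn, Ksi = Ksi),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (product-inhibition rate law)\n")
  cat(sprintf("  Vmax = %.4g uM/s   Km = %.4g uM   Kp = %.4g uM\n",
              x$Vmax * 1e6, x$Km * 1e6, x$Kp * 1e6))
  if (!is.null(x$kcat)) cat(sprintf("  kcat = %.4g /s\n", x$kcat))
  if (is.finite(x$dH_rxn)) cat(sprintf("  dH_rxn = %.4g kcal/mol\n", x$dH_rxn))
  if (!is.null(x$Ksi)) cat(sprintf("  Ksi = %.4g uM (substrate inhibition)\n", x$Ksi * 1e6))
  invisible(x)
}

#' Steady-state rate under competitive product inhibition
#'
#' Evaluates \eqn{v = Vmax \cdot S / (Km (1 + P/Kp) + S)}. With `P = 0` or
#' `Kp = Inf` this reduces to the plain Michaelis-Menten rate. When the
#' parameter set carries a substrate-inhibition constant Ksi the denominator
#' term S is replaced by \eqn{S (1 + S/Ksi)}.
#'
#' @param S substrate concentration (mol/L), scalar or vector, non-negative.
#' @param P product concentration (mol/L), scalar or vector, non-negative.
#' @param params a [kinetic_params()] object.
#' @return reaction rate (mol L^-1 s^-1), recycled over `S` and `P`.
#' @export
rate_product_inhibition <- function(S, P, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(S < 0) || any(P < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  km_eff <- params$Km * (1 + P / params$Kp)
  s_term <- if (is.null(params$Ksi)) S else S * (1 + S / params$Ksi)
  v <- params$Vmax * S / (km_eff + s_term)
  v[S == 0] <- 0
  v
}

#' Standard free energy of binding from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln(Kd / 1\,mol\,L^{-1})} with
#' R = 1.98720e-3 kcal mol^-1 K^-1; negative for sub-molar Kd.
#'
#' @param Kd dissociation constant (mol/L), positive.
#' @param T_K absolute temperature (K), positive.
#' @return free energy (kcal/mol).
#' @export
delta_g_from_kd <- function(Kd, T_K) {
  if (any(Kd <= 0)) stop("Kd must be positive", call. = FALSE)
  if (any(T_K <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  .R_KCAL * T_K * log(Kd)
}

#' Entropic term of binding from enthalpy and dissociation constant
#'
#' Returns \eqn{T\Delta S = \Delta H - \Delta G} with
#' \eqn{\Delta G = R T \ln Kd}.
#'
#' @param dH binding enthalpy (kcal/mol).
#' @inheritParams delta_g_from_kd
#' @return TdS (kcal/mol).
#' @export
tds_from <- function(dH, Kd, T_K) {
  dH - delta_g_from_kd(Kd, T_K)
}

#' Single-site binding parameter set with derived thermodynamics
#'
#' Holds stoichiometry n (sites per monomer), Kd, binding enthalpy and
#' temperature, with \eqn{\Delta G} and \eqn{T\Delta S} derived so that
#' \eqn{\Delta H - \Delta G - T\Delta S = 0} holds exactly by construction.
#'
#' @param n stoichiometry (sites per monomer), positive.
#' @param Kd dissociation constant (mol/L), positive.
#' @param dH binding enthalpy (kcal/mol).
#' @param T_K absolute temperature (K). `temp_C` may be given instead.
#' @param temp_C temperature in degrees Celsius (converted as K = C + 273.15).
#' @return an object of class `binding_params` with fields `n`, `Kd`, `dH`,
#'   `T_K`, `dG`, `TdS`.
#' @examples
#' binding_params(n = 1.12, Kd = 5.3e-6, dH = -5.5, temp_C = 30)
#' @export
binding_params <- function(n, Kd, dH, T_K = NULL, temp_C = NULL) {
  if (is.null(T_K)) {
    if (is.null(temp_C)) stop("supply T_K or temp_C", call. = FALSE)
    T_K <- temp_C + 273.15
  }
  if (!(n > 0)) stop("n must be positive", call. = FALSE)
  dG <- delta_g_from_kd(Kd, T_K)
  structure(list(n = n, Kd = Kd, dH = dH, T_K = T_K,
                 dG = dG, TdS = dH - dG),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat("Single-site binding parameters\n")
  cat(sprintf("  n = %.3f   Kd = %.3g uM   T = %.2f K\n",
              x$n, x$Kd * 1e6, x$T_K))
  cat(sprintf("  dH = %.2f  dG = %.2f  TdS = %.2f kcal/mol\n",
              x$dH, x$dG, x$TdS))
  invisible(x)
}
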