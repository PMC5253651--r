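#' @title Product-inhibition kinetic fitting
#' @name kinetics-fit-module
#' @description Nonlinear least-squares estimation of Km and Vmax (hence
#'   kcat) from a rate-versus-substrate profile under the competitive
#'   product-inhibition rate law with the product-affinity term Kp held
#'   fixed at an independently measured value. Product concentration at
#'   each point is reconstructed from 1:1 stoichiometry,
#'   P = P0 + (S0 - S).
NULL

#' Fit Km and Vmax under product inhibition with fixed Kp
#'
#' Minimizes \eqn{\sum_i (v_i - Vmax S_i / (Km (1 + P_i/Kp) + S_i))^2}
#' over (Km, Vmax) by Levenberg-Marquardt with positivity enforced through
#' log parameterization. Deterministic start: Vmax0 = 1.05 max(v), Km0 = S
#' at the point nearest half-maximal rate; on failure, bounded restarts
#' from 5 log-spaced Km0 values. Asymptotic standard errors come from the
#' Jacobian at the optimum. Unweighted least squares by default;
#' inverse-variance weights may be supplied.
#'
#' Profiles flagged as excess-limiting-substrate designs (prone to
#' apparent substrate inhibition) are refused unless `force = TRUE`.
#'
#' @param p an induction-trimmed [rate_profile()].
#' @param enzyme enzyme concentration (mol/L, monomers), used to derive
#'   kcat = Vmax / enzyme.
#' @param Kp fixed product-affinity term (mol/L); `Inf` reduces the model
#'   to plain Michaelis-Menten.
#' @param S0 starting limiting-substrate concentration (mol/L); defaults
#'   to the profile's own S0 attribute.
#' @param P0 starting product concentration (mol/L); defaults to the
#'   profile's P0 attribute (0 if absent).
#' @param weights optional per-point weights (e.g. inverse variances from
#'   replicate profiles).
#' @param force fit even if the profile is flagged excess-limiting.
#' @return an object of class `kinetics_fit` with components `Km`, `Vmax`,
#'   `kcat`, standard errors, `Kp_fixed`, `rss`, `n_points`, `converged`
#'   and a `narrow_range` warning flag (set when the fitted S values span
#'   less than 20% of S0, leaving Km poorly constrained).
#' @examples
#' kp <- kinetic_params(Vmax = 0.405e-6, Km = 1.1e-6, Kp = 6e-6)
#' S <- seq(0.2, 38, by = 0.5) * 1e-6
#' v <- rate_product_inhibition(S, 40e-6 - S, kp)
#' pr <- rate_profile(S, v, S0 = 40e-6)
#' fit_kinetics(pr, enzyme = 450e-9, Kp = 6e-6)
#' @export
fit_kinetics <- function(p, enzyme, Kp, S0 = attr(p, "S0"),
                         P0 = attr(p, "P0"), weights = NULL, force = FALSE) {
  stopifnot(inherits(p, "rate_profile"))
  if (isTRUE(attr(p, "excess_limiting")) && !force)
    stop("profile comes from an excess-limiting-substrate design ",
         "(apparent substrate inhibition); not regression-analysed ",
         "unless force = TRUE", call. = FALSE)
  if (is.null(P0) || is.na(P0)) P0 <- 0
  S <- p$S; v <- p$v
  ok <- is.finite(S) & is.finite(v) & S > 0
  S <- S[ok]; v <- v[ok]
  if (length(S) < 5) stop("fewer than 5 usable points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(S)) else weights <- weights[ok]
  P <- P0 + (S0 - S)
  P[P < 0] <- 0

  model_v <- function(Km, Vmax) Vmax * S / (Km * (1 + P / Kp) + S)
  resid_fn <- function(par)
    sqrt(weights) * (v - model_v(exp(par[["log_Km"]]), exp(par[["log_Vmax"]])))

  vmax0 <- 1.05 * max(v)
  km0 <- S[which.min(abs(v - max(v) / 2))]
  starts_km <- unique(c(km0, 10^seq(log10(max(km0 * 1e-2, 1e-12)),
                                    log10(km0 * 1e2), length.out = 5)))
  fit <- NULL
  for (k0 in starts_km) {
    cand <- minpack.lm::nls.lm(
      par = c(log_Km = log(k0), log_Vmax = log(vmax0)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500))
    if (!(cand$info %in% c(0, 5)) &&
        (is.null(fit) || cand$deviance < fit$deviance)) fit <- cand
    if (!is.null(fit) && fit$deviance <= 1e-24) break
  }
  if (is.null(fit))
    stop("fit failure: no convergent solution after bounded restarts ",
         "(tried ", length(starts_km), " Km starts)", call. = FALSE)

  Km_hat <- exp(fit$par[["log_Km"]])
  Vmax_hat <- exp(fit$par[["log_Vmax"]])
  dof <- length(S) - 2L
  sigma2 <- fit$deviance / max(dof, 1)
  cov_log <- tryCatch(sigma2 * solve(fit$hessian),
                      error = function(e) matrix(NA_real_, 2, 2))
  se_log <- sqrt(diag(cov_log))
  narrow <- (max(S) - min(S)) < 0.2 * S0
  if (narrow)
    warning("fitted S values span less than 20% of S0; Km is poorly constrained",
            call. = FALSE)

  structure(list(
    Km = Km_hat, Km_se = se_log[match("log_Km", names(fit$par))] * Km_hat,
    Vmax = Vmax_hat,
    Vmax_se = se_log[match("log_Vmax", names(fit$par))] * Vmax_hat,
    kcat = Vmax_hat / enzyme, enzyme = enzyme,
    Kp_fixed = Kp, S0 = S0, P0 = P0,
    rss = fit$deviance, n_points = length(S),
    converged = TRUE, narrow_range = narrow,
    data = data.frame(S = S, P = P, v = v,
                      fitted = model_v(Km_hat, Vmax_hat)),
    profile_source = attr(p, "source")),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("Product-inhibition kinetic fit (Kp fixed)\n")
  cat(sprintf("  Km   = %.3g +/- %.2g uM\n", x$Km * 1e6, x$Km_se * 1e6))
  cat(sprintf("  Vmax = %.3g +/- %.2g uM/s\n", x$Vmax * 1e6, x$Vmax_se * 1e6))
  cat(sprintf("  kcat = %.3g /s  ([E] = %.3g nM)\n", x$kcat, x$enzyme * 1e9))
  cat(sprintf("  Kp   = %.3g uM (fixed); RSS = %.4g over %d points\n",
              x$Kp_fixed * 1e6, x$rss, x$n_points))
  if (x$narrow_range)
    cat("  warning: narrow substrate coverage (< 20% of S0)\n")
  invisible(x)
}

#' @export
summary.kinetics_fit <- function(object, ...) {
  out <- list(km_uM = object$Km * 1e6, km_se = object$Km_se * 1e6,
              vmax_uM_per_s = object$Vmax * 1e6,
              vmax_se = object$Vmax_se * 1e6,
              kcat_per_s = object$kcat,
              kp_fixed_uM = object$Kp_fixed * 1e6,
              rss = object$rss, n_points = object$n_points,
              converged = object$converged,
              narrow_range = object$narrow_range)
  class(out) <- "summary.kinetics_fit"
  out
}

#' @export
print.summary.kinetics_fit <- function(x, ...) {
  utils::str(unclass(x), give.head = FALSE)
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  c(Km = object$Km, Vmax = object$Vmax, kcat = object$kcat)
}

#' @export
predict.kinetics_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$data$fitted)
  S <- newdata$S
  P <- if (!is.null(newdata$P)) newdata$P else object$P0 + (object$S0 - S)
  kp <- kinetic_params(Vmax = object$Vmax, Km = object$Km, Kp = object$Kp_fixed)
  rate_product_inhibition(S, pmax(P, 0), kp)
}

#' @export
residuals.kinetics_fit <- function(object, ...) {
  object$data$v - object$data$fitted
}

#' @export
plot.kinetics_fit <- function(x, ...) {
  d <- x$data[order(x$data$S), ]
  graphics::plot(d$S * 1e6, d$v * 1e6,
                 xlab = expression(paste("[S] (", mu, "M)")),
                 ylab = expression(paste("rate (", mu, "M ", s^-1, ")")), ...)
  graphics::lines(d$S * 1e6, d$fitted * 1e6, col = "red3", lwd = 2)
  invisible(x)
}
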