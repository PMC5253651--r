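#' @title Single-site ITC binding analysis
#' @name itc-module
#' @description Forward Wiseman single-site isotherm for an injection
#'   schedule in a fixed-volume perfusion cell, dilution-heat subtraction,
#'   and nonlinear least-squares fitting of (n, Kd, dH) with the low-c rule
#'   (n held at 1 when c = n [M]/Kd is too small for the inflection to
#'   constrain the stoichiometry).
NULL

#' Construct an ITC titration record
#'
#' @param V0 calorimetric cell volume (L).
#' @param M0 macromolecule (enzyme) concentration loaded in the cell
#'   (mol/L, monomers).
#' @param X_syr ligand concentration in the syringe (mol/L).
#' @param inj_vol per-injection volumes (L), e.g. 1 ul then 18 x 2 ul.
#' @param heats per-injection integrated heats (ucal); may be `NA` for a
#'   schedule awaiting simulation.
#' @param temp_C run temperature (deg C).
#' @param id character label.
#' @return an object of class `titration`.
#' @export
titration <- function(V0, M0, X_syr, inj_vol,
                      heats = rep(NA_real_, length(inj_vol)),
                      temp_C = 30, id = "titration") {
  if (!(V0 > 0)) stop("cell volume must be positive", call. = FALSE)
  if (any(inj_vol <= 0)) stop("injection volumes must be positive", call. = FALSE)
  if (length(heats) != length(inj_vol))
    stop("heats and injection volumes differ in length", call. = FALSE)
  if (sum(inj_vol) >= V0)
    stop("cumulative injected volume reaches the cell volume", call. = FALSE)
  structure(list(V0 = V0, M0 = M0, X_syr = X_syr,
                 inj_vol = as.numeric(inj_vol), heats = as.numeric(heats),
                 T_K = temp_C + 273.15, id = id),
            class = "titration")
}

#' The standard 1 + 18 x 2 ul injection schedule
#'
#' Convenience constructor for the customary schedule of a small first
#' injection followed by eighteen equal injections (37 ul total) into a
#' 204.1 ul cell.
#'
#' @inheritParams titration
#' @param n_main number of main injections (default 18).
#' @param first_ul,main_ul injection volumes in ul.
#' @export
titration_schedule <- function(M0, X_syr, V0 = 204.1e-6, first_ul = 1,
                               main_ul = 2, n_main = 18L, temp_C = 30,
                               id = "titration") {
  titration(V0 = V0, M0 = M0, X_syr = X_syr,
            inj_vol = c(first_ul, rep(main_ul, n_main)) * 1e-6,
            temp_C = temp_C, id = id)
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("Titration '%s': %d injections (%.3g ul total) into %.4g ul cell\n",
              x$id, length(x$inj_vol), sum(x$inj_vol) * 1e6, x$V0 * 1e6))
  cat(sprintf("  cell %.4g uM (monomers), syringe %.4g uM, %.1f K\n",
              x$M0 * 1e6, x$X_syr * 1e6, x$T_K))
  invisible(x)
}

#' Cell concentrations after each injection
#'
#' Standard displacement bookkeeping for a fixed-volume perfusion cell:
#' after cumulative injected volume dV the macromolecule concentration is
#' \eqn{M_0 (1 - dV/2V_0)/(1 + dV/2V_0)} and the total ligand concentration
#' \eqn{X_{syr} (dV/V_0) / (1 + dV/2V_0)}.
#'
#' @param t a [titration()].
#' @return data.frame with per-injection `dV_cum` (L), `M` and `X` (mol/L).
#' @export
injection_concentrations <- function(t) {
  stopifnot(inherits(t, "titration"))
  dV <- cumsum(t$inj_vol)
  r <- dV / (2 * t$V0)
  data.frame(dV_cum = dV,
             M = t$M0 * (1 - r) / (1 + r),
             X = t$X_syr * (dV / t$V0) / (1 + r))
}

# physical root (in [0,1]) of the Wiseman quadratic in the bound fraction
.theta_bound <- function(X, M, n, Kd) {
  b <- 1 + X / (n * M) + Kd / (n * M)
  c_ <- X / (n * M)
  disc <- b^2 - 4 * c_
  if (any(disc < 0)) stop("no physical root for bound fraction", call. = FALSE)
  th <- (b - sqrt(disc)) / 2
  if (any(th < -1e-12 | th > 1 + 1e-12))
    stop("bound fraction outside [0, 1]", call. = FALSE)
  pmin(pmax(th, 0), 1)
}

#' Predicted per-injection heats under the single-site model
#'
#' For each injection the fraction of sites occupied solves the Wiseman
#' quadratic \eqn{\Theta^2 - \Theta (1 + X/nM + Kd/nM) + X/nM = 0}
#' (physical root in [0, 1]); the cumulative heat is
#' \eqn{Q_i = n \Theta_i M_i \Delta H V_0} and the per-injection heat is
#' the difference of consecutive cumulative heats plus, optionally, the
#' standard fixed-cell displacement correction
#' \eqn{(dV_i/V_0)(Q_i + Q_{i-1})/2} accounting for heat carried out with
#' the expelled volume.
#'
#' @param t a [titration()] (its heats are ignored).
#' @param b a [binding_params()].
#' @param displacement apply the displacement correction (default TRUE).
#' @return numeric vector of per-injection heats (ucal).
#' @export
wiseman_heats <- function(t, b, displacement = TRUE) {
  stopifnot(inherits(t, "titration"), inherits(b, "binding_params"))
  conc <- injection_concentrations(t)
  theta <- .theta_bound(conc$X, conc$M, b$n, b$Kd)
  Q <- b$n * theta * conc$M * (b$dH * 1000) * t$V0  # cal
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev
  if (displacement) dQ <- dQ + (t$inj_vol / t$V0) * (Q + Qprev) / 2
  dQ * 1e6  # cal -> ucal
}

#' Subtract heats of dilution measured on a blank titration
#'
#' @param t ligand-into-macromolecule [titration()].
#' @param blank ligand-into-buffer titration with the identical injection
#'   schedule (count and volumes within 1%).
#' @return `t` with heats replaced by the elementwise difference.
#' @export
subtract_dilution <- function(t, blank) {
  stopifnot(inherits(t, "titration"), inherits(blank, "titration"))
  if (length(t$inj_vol) != length(blank$inj_vol) ||
      any(abs(t$inj_vol - blank$inj_vol) > 0.01 * t$inj_vol))
    stop("blank injection schedule does not match the titration", call. = FALSE)
  out <- t
  out$heats <- t$heats - blank$heats
  out
}

#' Fit the single-site binding model to a titration
#'
#' Nonlinear least squares of (n, Kd, dH) against the per-injection heats
#' via [wiseman_heats()] (Levenberg-Marquardt; n and Kd positive via log
#' parameterization). The customary small first injection is excluded by
#' default. If the Wiseman c value \eqn{c = n M_0 / Kd} of the free fit
#' falls below `c_min` (weak inflection), or `fix_n` is set, the
#' stoichiometry is held at 1 and only (Kd, dH) float. Free energy and
#' entropy are derived at the run temperature.
#'
#' @param t a dilution-subtracted [titration()] with observed heats.
#' @param fix_n force n = 1 regardless of c (default FALSE).
#' @param c_min c threshold below which n is fixed (default 5).
#' @param exclude_first drop the first injection from the fit (default TRUE).
#' @param displacement passed to [wiseman_heats()].
#' @return an object of class `binding_fit`; see [summary.binding_fit()].
#' @examples
#' b <- binding_params(n = 1.12, Kd = 5.3e-6, dH = -5.5, temp_C = 30)
#' t <- titration_schedule(M0 = 100e-6, X_syr = 1.5e-3)
#' t$heats <- wiseman_heats(t, b)
#' fit_binding(t)
#' @export
fit_binding <- function(t, fix_n = FALSE, c_min = 5, exclude_first = TRUE,
                        displacement = TRUE) {
  stopifnot(inherits(t, "titration"))
  use <- seq_along(t$heats)
  if (exclude_first) use <- use[-1]
  if (length(use) < 6) stop("fewer than 6 usable injections", call. = FALSE)
  obs <- t$heats[use]
  if (anyNA(obs)) stop("titration has missing heats", call. = FALSE)
  if (all(abs(obs) < 1e-9))
    stop("fit failure: no heat signal in the titration", call. = FALSE)

  conc <- injection_concentrations(t)
  # deterministic starts: dH from the first usable injection, Kd = M0/10
  mol_inj1 <- t$X_syr * t$inj_vol[use[1]]
  dH0 <- (obs[1] * 1e-6) / mol_inj1 / 1000        # kcal/mol
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
  Kd0 <- t$M0 / 10
  n0 <- 1

  pred_fun <- function(n, Kd, dH) {
    b <- binding_params(n = n, Kd = Kd, dH = dH, T_K = t$T_K)
    wiseman_heats(t, b, displacement = displacement)[use]
  }

  run_lm <- function(par0, n_fixed) {
    resid_fn <- function(par) {
      n <- if (n_fixed) 1 else exp(par[["log_n"]])
      obs - pred_fun(n, exp(par[["log_Kd"]]), par[["dH"]])
    }
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500))
  }

  free_par <- c(log_n = log(n0), log_Kd = log(Kd0), dH = dH0)
  fit <- if (fix_n) NULL else run_lm(free_par, n_fixed = FALSE)
  n_fixed <- fix_n
  if (!fix_n) {
    n_hat <- exp(fit$par[["log_n"]])
    Kd_hat <- exp(fit$par[["log_Kd"]])
    c_free <- n_hat * t$M0 / Kd_hat
    if (!is.finite(c_free) || c_free < c_min) n_fixed <- TRUE
  }
  if (n_fixed) {
    start <- if (!fix_n && !is.null(fit))
      c(log_Kd = fit$par[["log_Kd"]], dH = fit$par[["dH"]])
    else c(log_Kd = log(Kd0), dH = dH0)
    fit <- run_lm(start, n_fixed = TRUE)
    n_hat <- 1
    Kd_hat <- exp(fit$par[["log_Kd"]])
  } else {
    n_hat <- exp(fit$par[["log_n"]])
    Kd_hat <- exp(fit$par[["log_Kd"]])
  }
  if (fit$info %in% c(0, 5))
    stop("fit failure: Levenberg-Marquardt did not converge (info = ",
         fit$info, ")", call. = FALSE)
  dH_hat <- fit$par[["dH"]]

  # asymptotic standard errors; delta method back from the log scale
  np <- length(fit$par)
  dof <- length(obs) - np
  sigma2 <- sum(fit$fvec^2) / max(dof, 1)
  cov_log <- tryCatch(sigma2 * solve(fit$hessian),
                      error = function(e) matrix(NA_real_, np, np))
  se_of <- function(name) sqrt(diag(cov_log))[match(name, names(fit$par))]
  se <- list(
    n  = if (n_fixed) NA_real_ else se_of("log_n") * n_hat,
    Kd = se_of("log_Kd") * Kd_hat,
    dH = se_of("dH"))

  params <- binding_params(n = n_hat, Kd = Kd_hat, dH = dH_hat, T_K = t$T_K)
  structure(list(
    params = params, n_fixed = n_fixed,
    c_value = n_hat * t$M0 / Kd_hat, c_min = c_min,
    se = se, rss = sum(fit$fvec^2),
    fitted = pred_fun(n_hat, Kd_hat, dH_hat),
    observed = obs, used = use, titration = t,
    displacement = displacement, converged = !(fit$info %in% c(0, 5))),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  p <- x$params
  cat("Single-site ITC binding fit\n")
  cat(sprintf("  n  = %.3f%s\n", p$n,
              if (x$n_fixed) sprintf("  (held fixed: c = %.2g < %g)",
                                     x$c_value, x$c_min) else
                sprintf(" +/- %.3f", x$se$n)))
  cat(sprintf("  Kd = %.3g +/- %.2g uM\n", p$Kd * 1e6, x$se$Kd * 1e6))
  cat(sprintf("  dH = %.3g +/- %.2g kcal/mol\n", p$dH, x$se$dH))
  cat(sprintf("  dG = %.3g  TdS = %.3g kcal/mol  (T = %.2f K)\n",
              p$dG, p$TdS, p$T_K))
  cat(sprintf("  c = %.3g; RSS = %.4g ucal^2 over %d injections\n",
              x$c_value, x$rss, length(x$observed)))
  invisible(x)
}

#' Summarize a binding fit
#'
#' @param object a `binding_fit`.
#' @param ... unused.
#' @return a list with the parameter table, derived thermodynamics and fit
#'   diagnostics (also used for the JSON report).
#' @export
summary.binding_fit <- function(object, ...) {
  p <- object$params
  out <- list(n = p$n, n_fixed = object$n_fixed,
              n_se = object$se$n,
              kd_uM = p$Kd * 1e6, kd_se_uM = object$se$Kd * 1e6,
              dh_kcal_mol = p$dH, dh_se_kcal_mol = object$se$dH,
              dg_kcal_mol = p$dG, tds_kcal_mol = p$TdS,
              c_value = object$c_value, rss = object$rss,
              n_injections = length(object$observed),
              converged = object$converged)
  class(out) <- "summary.binding_fit"
  out
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  utils::str(unclass(x), give.head = FALSE)
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  p <- object$params
  c(n = p$n, Kd = p$Kd, dH = p$dH)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$titration else newdata
  wiseman_heats(t, object$params, displacement = object$displacement)
}

#' @export
residuals.binding_fit <- function(object, ...) {
  object$observed - object$fitted
}

#' @export
plot.binding_fit <- function(x, ...) {
  t <- x$titration
  conc <- injection_concentrations(t)[x$used, ]
  ratio <- conc$X / conc$M
  mol_inj <- t$X_syr * t$inj_vol[x$used]
  ndh_obs <- (x$observed * 1e-6) / mol_inj / 1000
  ndh_fit <- (x$fitted * 1e-6) / mol_inj / 1000
  graphics::plot(ratio, ndh_obs, xlab = "molar ratio [X]/[M]",
                 ylab = "kcal per mol of injectant", main = t$id, ...)
  graphics::lines(ratio, ndh_fit, col = "red3")
  invisible(x)
}
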