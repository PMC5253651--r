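#' @title Synthetic assay and titration generator
#' @name synthetic-module
#' @description Generates every input the pipeline consumes: single-
#'   injection assay thermograms by integrating the product-inhibition
#'   progress ODE, applying a first-order instrument response and additive
#'   power noise; and ITC titrations from the Wiseman forward model with a
#'   dilution offset and multiplicative heat noise. Every simulated object
#'   carries a ground-truth record for parameter-recovery testing.
NULL

#' Noise model for simulated data
#'
#' @param power_sd additive Gaussian noise on thermal power (ucal/s).
#' @param heat_frac multiplicative Gaussian noise fraction on per-injection
#'   heats.
#' @param seed integer seed; identical seeds reproduce identical outputs
#'   bit-for-bit. `NULL` leaves the RNG state alone.
#' @export
noise_model <- function(power_sd = 0, heat_frac = 0, seed = NULL) {
  if (power_sd < 0 || heat_frac < 0)
    stop("noise magnitudes must be non-negative", call. = FALSE)
  structure(list(power_sd = power_sd, heat_frac = heat_frac, seed = seed),
            class = "noise_model")
}

# smoothstep mixing ramp: 0 at t = 0, 1 at t >= width
.mixing_ramp <- function(t, width) {
  if (width <= 0) return(rep(1, length(t)))
  u <- pmin(pmax(t / width, 0), 1)
  u * u * (3 - 2 * u)
}

#' Dilution of syringe and cell contents on injection
#'
#' Injecting `V_inj` of syringe solution into a cell of volume `V_cell`
#' dilutes both streams by the combined volume: the injected species ends
#' at `syringe_conc * V_inj / (V_cell + V_inj)` and resident species at
#' `cell_conc * V_cell / (V_cell + V_inj)`.
#'
#' @param syringe_conc,cell_conc concentrations (mol/L).
#' @param V_cell,V_inj volumes (L).
#' @return list with `injected` and `resident` post-injection
#'   concentrations (mol/L).
#' @export
injection_dilution <- function(syringe_conc, cell_conc, V_cell, V_inj) {
  f <- V_cell + V_inj
  list(injected = syringe_conc * V_inj / f,
       resident = cell_conc * V_cell / f)
}

#' Integrate the reaction-progress ODE
#'
#' Integrates \eqn{dS/dt = -r(t) \, d(t) \, v(S, P_0 + S_0 - S)} with the
#' product-inhibition rate law, where `r(t)` is the smoothstep mixing ramp
#' over the injection transient and `d(t) = exp(-decay_rate t)` an optional
#' first-order loss of catalytic capacity (the deactivation mechanism used
#' as a classifier oracle). Integration uses `lsoda` at relative tolerance
#' 1e-9 and runs until less than `target_remaining` of the substrate is
#' left (the horizon doubles adaptively), or until `t_max` if the reaction
#' cannot complete.
#'
#' @param d an [assay_design()]; its `B0` is the limiting substrate.
#' @param k a [kinetic_params()] (must carry `dH_rxn` to emit heat).
#' @param dt output sampling interval (s), default 1.
#' @param transient_s mixing-transient width (s), default 20.
#' @param decay_rate first-order Vmax decay constant (1/s), default 0.
#' @param target_remaining completion criterion as a fraction of `B0`
#'   (default 0.005).
#' @param pad_s extra flat time appended after completion (s).
#' @param t_max hard ceiling on the simulated time (s).
#' @return a `progress_records` data.frame (`t, Q, S, P_prod, v`) with an
#'   extra column `A` (co-substrate by 1:1 stoichiometry) and attributes
#'   `S0`, `P0`, `dH`, `complete`.
#' @export
progress_ode <- function(d, k, dt = 1, transient_s = 20, decay_rate = 0,
                         target_remaining = 0.005, pad_s = 0, t_max = 2e5) {
  stopifnot(inherits(d, "assay_design"), inherits(k, "kinetic_params"))
  S0 <- d$B0; P0 <- d$P0
  rate_at <- function(t, S) {
    .mixing_ramp(t, transient_s) * exp(-decay_rate * t) *
      rate_product_inhibition(S, P0 + (S0 - S), k)
  }
  deriv <- function(t, y, parms) list(-rate_at(t, max(y[1], 0)))

  solve_to <- function(T_end) {
    times <- seq(0, T_end, by = dt)
    deSolve::ode(y = c(S = S0), times = times, func = deriv, parms = NULL,
                 method = "lsoda", rtol = 1e-9, atol = S0 * 1e-12,
                 hmax = 10 * dt)  # keeps steps on scale through the S -> 0 corner
  }

  if (k$Vmax <= 0) {
    times <- seq(0, min(600, t_max), by = dt)
    sol <- cbind(time = times, S = rep(S0, length(times)))
    complete <- FALSE
  } else {
    T_try <- min(max(4 * S0 / k$Vmax, 10 * dt) + transient_s, t_max)
    repeat {
      sol <- solve_to(T_try)
      complete <- sol[nrow(sol), "S"] < target_remaining * S0
      if (complete || T_try >= t_max) break
      T_try <- min(T_try * 2, t_max)
    }
    if (pad_s > 0) sol <- solve_to(T_try + pad_s)
  }
  t <- sol[, "time"]; S <- pmin(pmax(sol[, "S"], 0), S0)
  v <- vapply(seq_along(t), function(i) rate_at(t[i], S[i]), numeric(1))
  Q <- (S0 - S) * d$cell_volume * (k$dH_rxn * 1000)  # cal
  out <- data.frame(t = t, Q = Q, S = S, P_prod = P0 + (S0 - S), v = v,
                    A = d$A0 - (S0 - S))
  structure(out, class = c("progress_records", "data.frame"),
            S0 = S0, P0 = P0, dH = k$dH_rxn, source = d$label,
            injection_end_s = transient_s, complete = complete)
}

.mechanism_label <- function(k, decay_rate) {
  if (decay_rate > 0) "deactivation"
  else if (!is.null(k$Ksi)) "substrate_inhibition"
  else if (is.finite(k$Kp)) "product_inhibition"
  else "none"
}

#' Simulate a single-injection assay thermogram
#'
#' Runs [progress_ode()], converts the true rate into ideal thermal power
#' \eqn{P_{ideal}(t) = v(t) V \Delta H}, applies a first-order instrument
#' response with time constant `tau` (discrete recursive filter), adds
#' Gaussian power noise, and stamps the run metadata. Total heat before
#' noise equals \eqn{S_0 V \Delta H} because the mixing ramp modulates the
#' reaction rate, not the emitted heat.
#'
#' @inheritParams progress_ode
#' @param tau instrument time constant (s), default 10.
#' @param noise a [noise_model()].
#' @return list with `thermogram` (a [thermogram()]) and `truth` (a
#'   `ground_truth` list: `mechanism`, `params`, `decay_rate`,
#'   `transient_s`, `tau`, `noise`).
#' @export
simulate_assay <- function(d, k, tau = 10, noise = noise_model(), dt = 1,
                           transient_s = 20, decay_rate = 0,
                           pad_s = max(8 * tau, 60)) {
  stopifnot(inherits(d, "assay_design"), inherits(k, "kinetic_params"))
  if (!is.finite(k$dH_rxn) || k$dH_rxn == 0)
    stop("kinetic_params must carry a non-zero dH_rxn to emit power",
         call. = FALSE)
  pr <- progress_ode(d, k, dt = dt, transient_s = transient_s,
                     decay_rate = decay_rate, pad_s = pad_s)
  p_ideal <- pr$v * d$cell_volume * (k$dH_rxn * 1000) * 1e6  # ucal/s
  if (tau > 0) {
    a <- exp(-dt / tau)
    src <- (1 - a) * (c(p_ideal[1], (p_ideal[-1] + p_ideal[-length(p_ideal)]) / 2))
    p_meas <- as.numeric(stats::filter(src, a, method = "recursive"))
  } else p_meas <- p_ideal
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$power_sd > 0)
    p_meas <- p_meas + stats::rnorm(length(p_meas), 0, noise$power_sd)
  g <- thermogram(t = pr$t, power = p_meas, cell_volume = d$cell_volume,
                  enzyme = d$enzyme, S0 = d$B0, cosubstrate = d$A0,
                  P0 = d$P0, temp_K = d$temp_K,
                  injection_end_s = transient_s, id = d$label)
  truth <- structure(list(mechanism = .mechanism_label(k, decay_rate),
                          params = k, decay_rate = decay_rate,
                          transient_s = transient_s, tau = tau,
                          noise = noise, design = d,
                          complete = attr(pr, "complete")),
                     class = "ground_truth")
  list(thermogram = g, truth = truth, progress = pr)
}

#' Simulate an ITC titration with paired blank
#'
#' Per-injection heats from the Wiseman single-site forward model, plus an
#' optional constant dilution offset, plus multiplicative Gaussian noise.
#' A paired blank titration (offset and noise only) is emitted for
#' [subtract_dilution()] testing.
#'
#' @param schedule a [titration()] giving the injection schedule (heats
#'   ignored).
#' @param b a [binding_params()].
#' @param noise a [noise_model()] (`heat_frac` applies).
#' @param dilution_offset constant per-injection dilution heat (ucal).
#' @return list with `titration`, `blank` and `truth`.
#' @export
simulate_titration <- function(schedule, b, noise = noise_model(),
                               dilution_offset = 0) {
  stopifnot(inherits(schedule, "titration"), inherits(b, "binding_params"))
  ideal <- wiseman_heats(schedule, b)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  n <- length(ideal)
  mult <- if (noise$heat_frac > 0) 1 + stats::rnorm(n, 0, noise$heat_frac) else rep(1, n)
  blank_mult <- if (noise$heat_frac > 0) 1 + stats::rnorm(n, 0, noise$heat_frac) else rep(1, n)
  t_out <- schedule
  t_out$heats <- (ideal + dilution_offset) * mult
  blank <- schedule
  blank$heats <- dilution_offset * blank_mult
  blank$M0 <- 0
  blank$id <- paste0(schedule$id, "_blank")
  truth <- structure(list(mechanism = "binding", params = b,
                          dilution_offset = dilution_offset, noise = noise),
                     class = "ground_truth")
  list(titration = t_out, blank = blank, truth = truth)
}
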