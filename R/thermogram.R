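#' @title Thermogram processing
#' @name thermogram-module
#' @description Converts a raw calorimetric thermal-power trace into
#'   reaction-progress data: instrument time-constant correction, baseline
#'   subtraction, heat integration, molar reaction enthalpy, substrate and
#'   rate reconstruction, induction-period trimming and display binning.
#'
#'   Sign convention: exothermic reactions have negative molar enthalpy,
#'   negative power excursions and negative cumulative heat; rates and
#'   concentrations then come out positive.
NULL

#' Construct a reaction thermogram
#'
#' A thermogram is a thermal-power time series from a single-injection
#' calorimetric enzyme assay, plus the run metadata needed to convert it
#' into reaction-progress data.
#'
#' @param t time grid (s), strictly increasing, at least 10 samples.
#' @param power thermal power (ucal/s), signed (negative for exothermic).
#' @param cell_volume cell volume (L).
#' @param enzyme enzyme concentration in the cell (mol/L, monomers).
#' @param S0 limiting-substrate concentration immediately after injection
#'   (mol/L), positive.
#' @param cosubstrate co-substrate (saturating allylic substrate)
#'   concentration after injection (mol/L).
#' @param P0 product concentration present at the start (mol/L).
#' @param temp_K run temperature (K).
#' @param injection_end_s end of the injection/mixing transient (s).
#' @param id character label for provenance.
#' @return an object of class `thermogram`: list with `t`, `power` and
#'   `meta`.
#' @export
thermogram <- function(t, power, cell_volume, enzyme = NA_real_, S0,
                       cosubstrate = NA_real_, P0 = 0, temp_K = 303.15,
                       injection_end_s = 0, id = "thermogram") {
  t <- as.numeric(t); power <- as.numeric(power)
  if (length(t) != length(power)) stop("t and power lengths differ", call. = FALSE)
  if (length(t) < 10) stop("need at least 10 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (!(cell_volume > 0)) stop("cell volume must be positive", call. = FALSE)
  if (!(S0 > 0)) stop("S0 must be positive", call. = FALSE)
  structure(list(t = t, power = power,
                 meta = list(cell_volume = cell_volume, enzyme = enzyme,
                             S0 = S0, cosubstrate = cosubstrate, P0 = P0,
                             temp_K = temp_K, injection_end_s = injection_end_s,
                             id = id)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Thermogram '%s': %d samples, t = [%.4g, %.4g] s\n",
              m$id, length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  peak power %.4g ucal/s; cell %.4g ul; S0 %.4g uM; P0 %.4g uM\n",
              x$power[which.max(abs(x$power))], m$cell_volume * 1e6,
              m$S0 * 1e6, m$P0 * 1e6))
  invisible(x)
}

#' @export
plot.thermogram <- function(x, ...) {
  graphics::plot(x$t, x$power, type = "l", xlab = "time (s)",
                 ylab = expression(paste("thermal power (", mu, "cal ", s^-1, ")")),
                 main = x$meta$id, ...)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  invisible(x)
}

# centred moving average, ends padded by replication; window must be odd
.moving_average <- function(x, window = 5L) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    (half + 1L):(half + length(x))]
}

# central-difference derivative on a (possibly non-uniform) grid
.central_diff <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Correct a thermogram for the instrument response time
#'
#' A power-compensation calorimeter low-pass filters the true heat flow with
#' a first-order response of time constant `tau`. Inverting
#' \eqn{dP_{meas}/dt = (P_{true} - P_{meas})/\tau} gives
#' \eqn{P_{true}(t) = P_{meas}(t) + \tau \, dP_{meas}/dt}. The derivative is
#' taken by central differences on a 5-point moving-average-smoothed copy of
#' the trace.
#'
#' @param g a [thermogram()].
#' @param tau instrument time constant (s), non-negative; 0 returns the
#'   input unchanged.
#' @param smooth_window odd window length for the pre-derivative smoothing.
#' @return a `thermogram` on the same time grid with corrected power.
#' @export
correct_time_constant <- function(g, tau, smooth_window = 5L) {
  stopifnot(inherits(g, "thermogram"))
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (length(g$t) < 3) stop("need at least 3 samples", call. = FALSE)
  if (tau == 0) return(g)
  dp <- .central_diff(g$t, .moving_average(g$power, smooth_window))
  out <- g
  out$power <- g$power + tau * dp
  out
}

#' Integrate a thermogram to cumulative heat
#'
#' Trapezoidal accumulation of thermal power into cumulative heat. An
#' optional constant baseline, estimated as the mean power over a stated
#' time window, is subtracted first; drift beyond a constant offset is not
#' modelled.
#'
#' @param g a [thermogram()] (power in ucal/s).
#' @param baseline_window optional length-2 numeric `c(t0, t1)`: the mean
#'   power for `t0 <= t <= t1` is subtracted before integration. `NULL`
#'   (default) applies no baseline correction.
#' @return list with `Q_t` (cumulative heat in cal, same length as `g$t`)
#'   and `Q_total` (final heat, cal).
#' @export
integrate_heat <- function(g, baseline_window = NULL) {
  stopifnot(inherits(g, "thermogram"))
  p <- g$power
  if (!is.null(baseline_window)) {
    sel <- g$t >= baseline_window[1] & g$t <= baseline_window[2]
    if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
    p <- p - mean(p[sel])
  }
  dt <- diff(g$t)
  incr <- dt * (p[-1] + p[-length(p)]) / 2
  Q_t <- c(0, cumsum(incr)) * 1e-6  # ucal -> cal
  list(Q_t = Q_t, Q_total = Q_t[length(Q_t)])
}

#' Molar reaction enthalpy from total heat
#'
#' For a reaction run to completion, \eqn{\Delta H = Q_{total} / (S_0 V)}:
#' total heat divided by the moles of limiting substrate initially in the
#' cell.
#'
#' @param Q_total total integrated heat (cal).
#' @param S0 starting limiting-substrate concentration (mol/L).
#' @param V cell volume (L).
#' @return molar reaction enthalpy (kcal/mol).
#' @export
reaction_enthalpy <- function(Q_total, S0, V) {
  if (!(S0 > 0) || !(V > 0)) stop("S0 and V must be positive", call. = FALSE)
  if (Q_total == 0) stop("no detectable reaction heat (Q_total = 0)", call. = FALSE)
  Q_total / (S0 * V) / 1000
}

#' Substrate concentration from cumulative heat
#'
#' \eqn{S(t) = S_0 - Q(t)/(\Delta H \, V)}. Values outside `[0, S0]`
#' (noise-induced) are clipped; the number of clipped samples is attached
#' as attribute `n_clipped`.
#'
#' @param Q_t cumulative heat (cal).
#' @param dH molar reaction enthalpy (kcal/mol), non-zero.
#' @param V cell volume (L).
#' @param S0 starting limiting-substrate concentration (mol/L).
#' @return substrate concentration series (mol/L).
#' @export
substrate_concentration <- function(Q_t, dH, V, S0) {
  if (dH == 0) stop("dH must be non-zero", call. = FALSE)
  S <- S0 - Q_t / (dH * 1000 * V)
  n_clip <- sum(S < 0 | S > S0)
  S <- pmin(pmax(S, 0), S0)
  attr(S, "n_clipped") <- n_clip
  S
}

#' Reaction rate from thermal power
#'
#' \eqn{v(t) = (dQ/dt) / (\Delta H \, V)}; with the exothermic sign
#' convention both numerator and denominator are negative, so a well-signed
#' trace yields non-negative rates.
#'
#' @param g a [thermogram()] (power in ucal/s is dQ/dt).
#' @param dH molar reaction enthalpy (kcal/mol), non-zero.
#' @return rate series (mol L^-1 s^-1).
#' @export
reaction_rate <- function(g, dH) {
  stopifnot(inherits(g, "thermogram"))
  if (dH == 0) stop("dH must be non-zero", call. = FALSE)
  (g$power * 1e-6) / (dH * 1000 * g$meta$cell_volume)
}

#' Reaction-progress records from a thermogram
#'
#' Combines heat integration, substrate reconstruction and rate conversion
#' into one table: time, cumulative heat, remaining substrate, accumulated
#' product (initial product plus converted substrate, 1:1 stoichiometry)
#' and instantaneous rate.
#'
#' @inheritParams integrate_heat
#' @param dH molar reaction enthalpy (kcal/mol); if `NULL` it is estimated
#'   from the trace itself via [reaction_enthalpy()] (requires a complete
#'   reaction).
#' @return a data.frame of class `progress_records` with columns
#'   `t, Q, S, P_prod, v` and attributes `S0`, `P0`, `dH`, `source`.
#' @export
progress_records <- function(g, dH = NULL, baseline_window = NULL) {
  stopifnot(inherits(g, "thermogram"))
  m <- g$meta
  h <- integrate_heat(g, baseline_window)
  if (is.null(dH)) dH <- reaction_enthalpy(h$Q_total, m$S0, m$cell_volume)
  S <- substrate_concentration(h$Q_t, dH, m$cell_volume, m$S0)
  v <- reaction_rate(g, dH)
  out <- data.frame(t = g$t, Q = h$Q_t, S = as.numeric(S),
                    P_prod = m$P0 + (m$S0 - as.numeric(S)), v = v)
  structure(out, class = c("progress_records", "data.frame"),
            S0 = m$S0, P0 = m$P0, dH = dH, source = m$id,
            injection_end_s = m$injection_end_s,
            n_clipped = attr(S, "n_clipped"))
}

#' Rate-versus-substrate profile
#'
#' Ordered (substrate concentration, rate) pairs derived from one
#' thermogram, with provenance on how they were produced.
#'
#' @param S substrate concentrations (mol/L).
#' @param v rates (mol L^-1 s^-1).
#' @param t optional time stamps (s).
#' @param source character id of the source thermogram.
#' @param S0 starting substrate concentration (mol/L), used for coverage
#'   diagnostics.
#' @param P0 starting product concentration (mol/L).
#' @param trimmed,binned bookkeeping flags.
#' @param excess_limiting logical: was this run designed with the limiting
#'   substrate in excess (flags substrate-inhibition-prone data that the
#'   kinetic fitter refuses by default)?
#' @return a data.frame of class `rate_profile`.
#' @export
rate_profile <- function(S, v, t = NULL, source = "profile", S0 = max(S),
                         P0 = 0, trimmed = FALSE, binned = NA_integer_,
                         excess_limiting = FALSE) {
  df <- if (is.null(t)) data.frame(S = S, v = v) else data.frame(t = t, S = S, v = v)
  structure(df, class = c("rate_profile", "data.frame"),
            source = source, S0 = S0, P0 = P0, trimmed = trimmed,
            binned = binned, excess_limiting = excess_limiting)
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("Rate profile '%s': %d points, S = [%.4g, %.4g] uM%s%s\n",
              attr(x, "source"), nrow(x), min(x$S) * 1e6, max(x$S) * 1e6,
              if (isTRUE(attr(x, "trimmed"))) ", induction-trimmed" else "",
              if (!is.na(attr(x, "binned"))) sprintf(", binned k=%d", attr(x, "binned")) else ""))
  invisible(x)
}

#' @export
plot.rate_profile <- function(x, ...) {
  graphics::plot(x$S * 1e6, x$v * 1e6, xlab = expression(paste("[S] (", mu, "M)")),
                 ylab = expression(paste("rate (", mu, "M ", s^-1, ")")),
                 main = attr(x, "source"), ...)
  invisible(x)
}

#' Convert progress records to a rate profile
#'
#' @param p a [progress_records()] table.
#' @param excess_limiting see [rate_profile()].
#' @return a `rate_profile` retaining time stamps.
#' @export
as_rate_profile <- function(p, excess_limiting = FALSE) {
  stopifnot(inherits(p, "progress_records"))
  rate_profile(S = p$S, v = p$v, t = p$t, source = attr(p, "source"),
               S0 = attr(p, "S0"), P0 = attr(p, "P0"),
               excess_limiting = excess_limiting)
}

#' Drop the induction period from a progress series
#'
#' Removes all points recorded before the system reaches steady-state
#' behaviour. With `rule = "fixed"` the cutoff is the injection end time
#' plus `extra` seconds. With `rule = "auto"` the cutoff is the first time
#' the smoothed power magnitude is within 2% of its monotone-decay trend
#' (the running maximum taken from the right), i.e. the onset of the
#' post-peak decay.
#'
#' @param x a `progress_records` or `rate_profile` with a `t` column.
#' @param rule `"fixed"` (default) or `"auto"`.
#' @param extra seconds added to the injection end time under the fixed
#'   rule (default 30).
#' @param injection_end injection end time (s); defaults to the value
#'   carried by the input's metadata.
#' @param power optional power series aligned with `x$t`, required for
#'   `rule = "auto"` when `x` is a rate profile (for progress records the
#'   rate column is used).
#' @param settle_s under the auto rule, minimum time after the injection
#'   end before any point is considered steady (default 0).
#' @return the same type with pre-cutoff rows removed; errors if nothing
#'   survives.
#' @export
trim_induction <- function(x, rule = c("fixed", "auto"), extra = 30,
                           injection_end = NULL, power = NULL,
                           settle_s = 0) {
  rule <- match.arg(rule)
  if (!("t" %in% names(x))) stop("input has no time column", call. = FALSE)
  if (is.null(injection_end)) injection_end <- attr(x, "injection_end_s")
  if (rule == "fixed") {
    if (is.null(injection_end))
      stop("injection end time required for the fixed rule", call. = FALSE)
    cutoff <- injection_end + extra
  } else {
    m <- if (!is.null(power)) abs(power) else abs(x$v)
    ms <- .moving_average(m, 5L)
    run_max_right <- rev(cummax(rev(ms)))
    steady <- ms >= 0.98 * run_max_right
    if (!any(steady)) stop("no steady-state region found", call. = FALSE)
    cutoff <- x$t[which(steady)[1]]
    # nothing during the injection itself is steady, whatever the trace says
    if (!is.null(injection_end))
      cutoff <- max(cutoff, injection_end + settle_s)
  }
  keep <- x$t >= cutoff
  if (!any(keep))
    stop("induction cutoff removes all data points", call. = FALSE)
  out <- x[keep, , drop = FALSE]
  for (a in setdiff(names(attributes(x)), c("names", "row.names", "class")))
    attr(out, a) <- attr(x, a)
  attr(out, "trimmed") <- TRUE
  out
}

#' Bin a rate profile for display
#'
#' Replaces consecutive non-overlapping groups of `k` points by their
#' arithmetic mean (in both S and v); a trailing incomplete group is
#' dropped. `k = 1` is the identity.
#'
#' @param p a [rate_profile()].
#' @param k bin size (default 5).
#' @return a binned `rate_profile`.
#' @export
bin_rates <- function(p, k = 5L) {
  stopifnot(inherits(p, "rate_profile"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k == 1L) return(p)
  n <- (nrow(p) %/% k) * k
  if (n == 0L) stop("fewer points than one bin", call. = FALSE)
  grp <- rep(seq_len(n %/% k), each = k)
  agg <- function(col) as.numeric(tapply(col[seq_len(n)], grp, mean))
  out <- rate_profile(S = agg(p$S), v = agg(p$v),
                      t = if ("t" %in% names(p)) agg(p$t) else NULL,
                      source = attr(p, "source"), S0 = attr(p, "S0"),
                      P0 = attr(p, "P0"), trimmed = attr(p, "trimmed"),
                      binned = k, excess_limiting = attr(p, "excess_limiting"))
  out
}

#' Full thermogram-to-rates pipeline
#'
#' Applies, in order: time-constant correction, baseline subtraction and
#' heat integration, molar-enthalpy determination (unless supplied),
#' substrate/rate reconstruction, and induction trimming. This is the
#' standard route from a raw single-injection trace to the rate profile
#' consumed by [fit_kinetics()] and [overlay_metric()].
#'
#' @inheritParams progress_records
#' @param tau instrument time constant (s), default 10.
#' @param trim_rule,trim_extra passed to [trim_induction()].
#' @param excess_limiting flag propagated to the profile (see
#'   [rate_profile()]).
#' @return an induction-trimmed `rate_profile` (unbinned); the determined
#'   enthalpy is attached as attribute `dH`.
#' @export
process_thermogram <- function(g, tau = 10, dH = NULL, baseline_window = NULL,
                               trim_rule = "fixed", trim_extra = 30,
                               excess_limiting = FALSE) {
  gc_ <- correct_time_constant(g, tau)
  pr <- progress_records(gc_, dH = dH, baseline_window = baseline_window)
  pr <- trim_induction(pr, rule = trim_rule, extra = trim_extra,
                       injection_end = g$meta$injection_end_s,
                       power = if (trim_rule == "auto") gc_$power else NULL)
  prof <- as_rate_profile(pr, excess_limiting = excess_limiting)
  attr(prof, "dH") <- attr(pr, "dH")
  prof
}
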