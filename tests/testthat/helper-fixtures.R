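# Shared fixtures: the study conditions used throughout the suite, and the
# independent oracles (RK4 integrator, bisection equilibrium solver,
# stepwise dilution simulator) that cross-check the analytical paths.

# kinetic parameter set of the excess-GPP assay: kcat 0.90/s at 450 nM
# enzyme, Km(IPP) 1.1 uM, product affinity 6 uM, reaction enthalpy
# -22.5 kcal/mol
study_kin <- function(Kp = 6e-6, dH = -22.5, Ksi = NULL) {
  kinetic_params(kcat = 0.90, enzyme = 450e-9, Km = 1.1e-6, Kp = Kp,
                 dH_rxn = dH, Ksi = Ksi)
}

# single-site binding parameter sets (30 C) as tabulated by ITC
fpp_binding  <- function() binding_params(n = 1.12, Kd = 5.3e-6, dH = -5.5, temp_C = 30)
gpp_mg_binding <- function() binding_params(n = 0.79, Kd = 2.1e-6, dH = -7.7, temp_C = 30)
dmapp_binding <- function() binding_params(n = 1, Kd = 43.7e-6, dH = -4.5, temp_C = 30)

study_pair <- function() design_same_excess(24e-6, c(16e-6, 40e-6))[[1]]

# independent fixed-step RK4 integration of dS/dt = -ramp(t) * v(S, P)
rk4_progress <- function(d, k, h = 0.02, transient_s = 20, t_end = 2000) {
  ramp <- function(t) {
    u <- pmin(pmax(t / transient_s, 0), 1)
    u * u * (3 - 2 * u)
  }
  f <- function(t, S) {
    S <- max(S, 0)
    -ramp(t) * rate_product_inhibition(S, d$P0 + (d$B0 - S), k)
  }
  n <- ceiling(t_end / h)
  t <- numeric(n + 1); S <- numeric(n + 1)
  S[1] <- d$B0
  for (i in seq_len(n)) {
    k1 <- f(t[i], S[i])
    k2 <- f(t[i] + h / 2, S[i] + h * k1 / 2)
    k3 <- f(t[i] + h / 2, S[i] + h * k2 / 2)
    k4 <- f(t[i] + h, S[i] + h * k3)
    S[i + 1] <- S[i] + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    t[i + 1] <- t[i] + h
    if (S[i + 1] < 1e-4 * d$B0) { t <- t[1:(i + 1)]; S <- S[1:(i + 1)]; break }
  }
  data.frame(t = t, S = S)
}

# time at which a trajectory crosses a substrate level (linear interpolation)
crossing_time <- function(t, S, level) {
  i <- which(S <= level)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  t[i - 1] + (t[i] - t[i - 1]) * (S[i - 1] - level) / (S[i - 1] - S[i])
}

# brute-force equilibrium: free ligand x solves x + n*M*x/(Kd + x) = X_tot,
# bound fraction of sites = x/(Kd + x); bisection to machine precision
theta_bisect <- function(X, M, n, Kd) {
  vapply(seq_along(X), function(i) {
    g <- function(x) x + n * M[i] * x / (Kd + x) - X[i]
    if (X[i] <= 0) return(0)
    lo <- 0; hi <- X[i]
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    mid <- (lo + hi) / 2
    mid / (Kd + mid)
  }, numeric(1))
}

# stepwise inject-mix-expel simulation of a fixed-volume perfusion cell
stepwise_dilution <- function(V0, M0, X_syr, inj_vol) {
  M <- M0; X <- 0
  for (dv in inj_vol) {
    M <- M * V0 / (V0 + dv)
    X <- (X * V0 + X_syr * dv) / (V0 + dv)
  }
  list(M = M, X = X)
}
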