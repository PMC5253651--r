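test_that("displacement bookkeeping matches a stepwise inject-mix-expel simulation", {
  t <- titration_schedule(M0 = 100e-6, X_syr = 1.5e-3)
  conc <- injection_concentrations(t)
  # monotone in the expected directions
  expect_true(all(diff(conc$M) < 0))
  expect_true(all(diff(conc$X) > 0))
  # first-order limit for a small injection
  t1 <- titration(V0 = 204.1e-6, M0 = 100e-6, X_syr = 1e-3,
                  inj_vol = c(0.1e-6, rep(1e-6, 9)))
  c1 <- injection_concentrations(t1)
  expect_equal(c1$X[1], 1e-3 * 0.1 / 204.1, tolerance = 1e-3)
  # full 37 ul schedule against the brute-force oracle
  oracle <- stepwise_dilution(204.1e-6, 100e-6, 1.5e-3, t$inj_vol)
  n <- nrow(conc)
  expect_equal(conc$M[n], oracle$M, tolerance = 5e-3)
  expect_equal(conc$X[n], oracle$X, tolerance = 5e-3)
  expect_error(titration(V0 = 10e-6, M0 = 1e-6, X_syr = 1e-3,
                         inj_vol = rep(2e-6, 6)), "cell volume")
})

test_that("Wiseman forward model: limits and the bisection oracle", {
  t <- titration_schedule(M0 = 100e-6, X_syr = 1.5e-3)
  # zero enthalpy -> zero heats
  b0 <- binding_params(n = 1, Kd = 5e-6, dH = 0, temp_C = 30)
  expect_equal(wiseman_heats(t, b0), rep(0, 19))
  # stoichiometric (tight-binding) limit: each injection delivers
  # moles * dH until saturation, then nothing
  bt <- binding_params(n = 1, Kd = 1e-12, dH = -5, temp_C = 30)
  ht <- wiseman_heats(t, bt, displacement = FALSE)
  mol2 <- 1.5e-3 * 2e-6
  expect_equal(ht[2] * 1e-6, mol2 * (-5 * 1000), tolerance = 0.02)
  # post-saturation heats are small (not exactly zero: expelled complex
  # still changes the cumulative bookkeeping slightly)
  expect_lt(abs(ht[19]), abs(ht[2]) * 0.1)
  # single-point bound fraction: n=1, M=100 uM, Kd=5.3 uM, X=50 uM
  th <- theta_bisect(50e-6, 100e-6, 1, 5.3e-6)
  expect_equal(th, 0.456, tolerance = 1e-3)
})

test_that("forward model agrees with the equilibrium oracle over random draws", {
  set.seed(21)
  for (i in 1:100) {
    n <- runif(1, 0.5, 2)
    Kd <- 10^runif(1, -8, -3.5)
    M0 <- 10^runif(1, -5, -3.5)
    X_syr <- M0 * runif(1, 5, 30)
    b <- binding_params(n = n, Kd = Kd, dH = runif(1, -10, -1), temp_C = 30)
    t <- titration_schedule(M0 = M0, X_syr = X_syr)
    conc <- injection_concentrations(t)
    theta_quad <- (function() {
      # recompute from cumulative heats: theta = Q / (n M dH V0)
      Q <- cumsum(wiseman_heats(t, b, displacement = FALSE)) * 1e-6
      Q / (b$n * conc$M * (b$dH * 1000) * t$V0)
    })()
    theta_or <- theta_bisect(conc$X, b$n * conc$M, 1, Kd)
    expect_true(all(theta_quad >= 0 & theta_quad <= 1))
    expect_true(all(diff(theta_quad) >= -1e-12))
    expect_lt(max(abs(theta_quad - theta_or)), 1e-8)
  }
})

test_that("per-injection heats telescope to the final cumulative heat", {
  b <- fpp_binding()
  t <- titration_schedule(M0 = 100e-6, X_syr = 1.5e-3)
  conc <- injection_concentrations(t)
  dq <- wiseman_heats(t, b, displacement = FALSE) * 1e-6
  n <- nrow(conc)
  theta_n <- theta_bisect(conc$X[n], b$n * conc$M[n], 1, b$Kd)
  Q_final <- b$n * theta_n * conc$M[n] * (b$dH * 1000) * t$V0
  expect_equal(sum(dq), Q_final, tolerance = 1e-8)
})

test_that("dilution subtraction recovers offset-free heats", {
  b <- fpp_binding()
  sched <- titration_schedule(M0 = 100e-6, X_syr = 1.5e-3)
  sim <- simulate_titration(sched, b, dilution_offset = 0.2)
  clean <- subtract_dilution(sim$titration, sim$blank)
  expect_equal(clean$heats, wiseman_heats(sched, b), tolerance = 1e-12)
  # identical blank zeroes everything
  z <- subtract_dilution(sim$titration, sim$titration)
  expect_equal(z$heats, rep(0, 19))
  # schedule mismatch refused
  bad <- sim$blank
  bad$inj_vol[3] <- bad$inj_vol[3] * 1.5
  expect_error(subtract_dilution(sim$titration, bad), "schedule")
})

test_that("noiseless titrations are fitted back to the generating parameters", {
  for (b in list(fpp_binding(), gpp_mg_binding())) {
    sched <- titration_schedule(M0 = 100e-6,
                                X_syr = if (b$Kd < 3e-6) 1e-3 else 1.5e-3)
    sim <- simulate_titration(sched, b)
    fit <- fit_binding(sim$titration)
    expect_equal(fit$params$n, b$n, tolerance = 5e-3)
    expect_equal(fit$params$Kd, b$Kd, tolerance = 5e-3)
    expect_equal(fit$params$dH, b$dH, tolerance = 5e-3)
    expect_false(fit$n_fixed)
    # derived thermodynamics close exactly
    expect_equal(fit$params$dH - fit$params$dG - fit$params$TdS, 0)
  }
})

test_that("the low-c rule fixes the stoichiometry for weak binding", {
  b <- dmapp_binding()  # c = 100/43.7, about 2.3
  sim <- simulate_titration(titration_schedule(M0 = 100e-6, X_syr = 1.5e-3), b)
  fit <- fit_binding(sim$titration)
  expect_true(fit$n_fixed)
  expect_identical(fit$params$n, 1)
  expect_lt(fit$c_value, 5)
  expect_equal(fit$params$Kd, 43.7e-6, tolerance = 5e-3)
  # all-zero heats cannot be fitted
  flat <- sim$titration
  flat$heats[] <- 0
  expect_error(fit_binding(flat), "fit failure")
})

test_that("Kd is recovered within 10% median under 2% heat noise across c", {
  set.seed(31)
  errs <- vapply(1:50, function(s) {
    c_target <- 10^runif(1, log10(2), log10(50))
    Kd <- 100e-6 / c_target
    b <- binding_params(n = 1, Kd = Kd, dH = -6, temp_C = 30)
    sim <- simulate_titration(titration_schedule(M0 = 100e-6, X_syr = 1.5e-3),
                              b, noise = noise_model(heat_frac = 0.02,
                                                     seed = 800 + s))
    fit <- fit_binding(sim$titration)
    abs(fit$params$Kd / Kd - 1)
  }, numeric(1))
  expect_lte(stats::median(errs), 0.10)
})

test_that("triplicate scatter at 2% noise is of the tabulated order", {
  b <- fpp_binding()
  sched <- titration_schedule(M0 = 100e-6, X_syr = 1.5e-3)
  kds <- vapply(1:3, function(s) {
    sim <- simulate_titration(sched, b,
                              noise = noise_model(heat_frac = 0.02, seed = s))
    fit_binding(sim$titration)$params$Kd
  }, numeric(1)) * 1e6
  # tabulated uncertainty for this system is a few tenths of a uM
  expect_lt(stats::sd(kds), 1)
  expect_equal(mean(kds), 5.3, tolerance = 0.1)
})

test_that("binding_fit methods are coherent", {
  b <- fpp_binding()
  sched <- titration_schedule(M0 = 100e-6, X_syr = 1.5e-3)
  sim <- simulate_titration(sched, b,
                            noise = noise_model(heat_frac = 0.02, seed = 5))
  fit <- fit_binding(sim$titration)
  expect_named(coef(fit), c("n", "Kd", "dH"))
  expect_length(predict(fit), 19)
  expect_equal(length(residuals(fit)), 18)  # first injection excluded
  s <- summary(fit)
  expect_equal(s$kd_uM, fit$params$Kd * 1e6)
  expect_output(print(fit), "Kd")
})
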