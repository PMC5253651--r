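make_gram <- function(t, p, S0 = 20e-6, inj_end = 0, ...)
  thermogram(t, p, cell_volume = 204.1e-6, S0 = S0,
             injection_end_s = inj_end, ...)

test_that("time-constant correction: identity, constant, and step inversion", {
  t <- 0:100
  g <- make_gram(t, -2 + 0.01 * t)
  expect_identical(correct_time_constant(g, 0), g)
  gc_ <- correct_time_constant(make_gram(t, rep(-1.5, 101)), 12)
  expect_equal(gc_$power, rep(-1.5, 101), tolerance = 1e-12)
  # first-order step response recovers the step
  tau <- 10; P0 <- -3
  gs <- make_gram(t, P0 * (1 - exp(-t / tau)))
  rec <- correct_time_constant(gs, tau)$power
  interior <- t >= 5 & t <= 50
  expect_lt(max(abs(rec[interior] - P0)), 0.02 * abs(P0))
  expect_error(correct_time_constant(g, -1), "non-negative")
})

test_that("convolve/deconvolve round trip recovers the ideal trace", {
  t <- 0:400
  ideal <- -2.5 * exp(-((t - 120) / 45)^2)  # smooth pulse decaying at both ends
  for (tau in c(2, 7, 20)) {
    a <- exp(-1 / tau)
    src <- (1 - a) * c(ideal[1], (ideal[-1] + ideal[-length(ideal)]) / 2)
    meas <- as.numeric(stats::filter(src, a, method = "recursive"))
    rec <- correct_time_constant(make_gram(t, meas), tau)$power
    sel <- t > 2 * tau
    expect_lt(max(abs(rec[sel] - ideal[sel])), 0.01 * max(abs(ideal)))
    # integrated heat preserved by the correction
    q_meas <- integrate_heat(make_gram(t, meas))$Q_total
    q_rec <- integrate_heat(make_gram(t, rec))$Q_total
    expect_equal(q_rec, q_meas, tolerance = 5e-3)
  }
})

test_that("heat integration handles zero, rectangular, and baseline cases", {
  t <- 0:99
  expect_equal(integrate_heat(make_gram(t, rep(0, 100)))$Q_total, 0)
  # rectangular pulse: -2 ucal/s sustained for 50 s = -100 ucal
  expect_equal(integrate_heat(make_gram(seq(0, 50, 5), rep(-2, 11)))$Q_total * 1e6,
               -100)
  # constant baseline subtracted over a stated window
  p <- ifelse(t < 50, -2, 0)
  q2 <- sum(diff(t) * (p[-1] + p[-100]) / 2)
  qb <- integrate_heat(make_gram(t, p + 0.5),
                       baseline_window = c(60, 99))$Q_total
  expect_equal(qb * 1e6, q2)
})

test_that("molar enthalpy follows Q_total/(S0 V)", {
  expect_equal(reaction_enthalpy(-91.85e-6, 20e-6, 204.1e-6), -22.5,
               tolerance = 1e-3)
  # inverse identity
  expect_equal(reaction_enthalpy(16e-6 * 204.1e-6 * (-22.3 * 1000),
                                 16e-6, 204.1e-6), -22.3)
  expect_error(reaction_enthalpy(0, 1e-6, 1e-6), "no detectable")
})

test_that("substrate reconstruction is linear in heat and clips noise", {
  Qt <- c(0, -0.5, -1, -1.5, -2) * 91.85e-6 / 2
  S <- substrate_concentration(Qt, -22.5012, 204.1e-6, 20e-6)
  expect_equal(S[1], 20e-6)
  expect_equal(S[3], 10e-6, tolerance = 1e-4)
  expect_equal(S[5], 0, tolerance = 1e-4 * 20e-6)
  # overshoot clipped and counted
  S2 <- substrate_concentration(c(0, -2.2 * 91.85e-6 / 2), -22.5012,
                                204.1e-6, 20e-6)
  expect_identical(as.numeric(S2[2]), 0)
  expect_identical(attr(S2, "n_clipped"), 1L)
  expect_error(substrate_concentration(Qt, 0, 1e-6, 1e-6), "non-zero")
})

test_that("rate conversion matches dQ/dt / (dH V)", {
  g <- make_gram(0:9, rep(-2, 10))
  v <- reaction_rate(g, -22.5)
  expect_equal(v[1] * 1e6, 0.436, tolerance = 2e-3)
  expect_equal(reaction_rate(make_gram(0:9, rep(0, 10)), -22.5),
               rep(0, 10))
  expect_true(all(v > 0))  # exothermic sign convention gives positive rates
})

test_that("induction trimming obeys fixed and auto rules and degenerates", {
  pr <- structure(data.frame(t = 0:59, Q = 0, S = 1e-6, P_prod = 0,
                             v = 1e-8),
                  class = c("progress_records", "data.frame"),
                  injection_end_s = 0)
  expect_equal(nrow(trim_induction(pr, extra = 30)), 30)
  # already steady from t = 0: auto rule keeps everything (monotone decay)
  pr2 <- pr; pr2$v <- seq(1e-7, 1e-8, length.out = 60)
  expect_equal(nrow(trim_induction(pr2, rule = "auto")), 60)
  # cutoff that removes everything errors
  short <- pr[1:20, ]
  attr(short, "injection_end_s") <- 0
  class(short) <- class(pr)
  expect_error(trim_induction(short, extra = 30), "removes all")
  # synthetic run: the 30 s transient window is gone under the fixed rule
  sim <- simulate_assay(study_pair()$run_high, study_kin(), tau = 10,
                        transient_s = 30)
  pp <- progress_records(correct_time_constant(sim$thermogram, 10))
  trimmed <- trim_induction(pp, extra = 30,
                            injection_end = sim$thermogram$meta$injection_end_s)
  expect_gte(min(trimmed$t), 60)
})

test_that("binning averages complete groups and drops the remainder", {
  p <- rate_profile(S = (1:12) * 1e-6, v = (12:1) * 1e-8, S0 = 12e-6)
  b5 <- bin_rates(p, 5)
  expect_equal(nrow(b5), 2)
  expect_equal(b5$S, c(mean(1:5), mean(6:10)) * 1e-6)
  expect_equal(b5$v, c(mean(12:8), mean(7:3)) * 1e-8)
  expect_identical(bin_rates(p, 1), p)
  p10 <- rate_profile(S = (1:10) * 1e-6, v = rep(1e-8, 10))
  expect_equal(nrow(bin_rates(p10, 5)), 2)
  expect_error(bin_rates(p, 0), "at least 1")
})

test_that("full synthetic run conserves heat, mass, and rate consistency", {
  kin <- study_kin()
  d <- study_pair()$run_high
  sim <- simulate_assay(d, kin, tau = 10)
  # conservation: total heat = S0 * V * dH within 0.5%
  q <- integrate_heat(correct_time_constant(sim$thermogram, 10))$Q_total
  expect_equal(q / (d$B0 * d$cell_volume * (-22.5 * 1000)), 1,
               tolerance = 5e-3)
  pr <- progress_records(correct_time_constant(sim$thermogram, 10))
  expect_lt(pr$S[nrow(pr)], 0.01 * d$B0)
  expect_equal(attr(pr, "dH"), -22.5, tolerance = 5e-3)
  # mass balance at every sample
  expect_lt(max(abs(pr$S + (pr$P_prod - attr(pr, "P0")) - d$B0)),
            1e-3 * d$B0)
  # d[S]/dt equals -v where the reaction is running appreciably
  trimmed <- trim_induction(pr, extra = 30)
  dS <- -(trimmed$S[-c(1, 2)] - trimmed$S[-c(nrow(trimmed) - 1, nrow(trimmed))]) / 2
  v_mid <- trimmed$v[-c(1, nrow(trimmed))]
  sel <- v_mid > 0.05 * max(v_mid)
  expect_lt(max(abs(dS[sel] / v_mid[sel] - 1)), 0.01)
})
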