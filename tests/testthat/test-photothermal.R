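pars <- function(...) lumped_thermal_params(tau_c_s = 180, q_dis_mW = 10,
                                            I_mW = 2000, ...)

test_that("lumped forward model matches its closed forms", {
  p0 <- lumped_thermal_params(tau_c_s = 180, q_dis_mW = 0, I_mW = 2000)
  tr <- simulate_heating(p0, eta = 0, on_s = 100, off_s = 100)
  expect_true(all(tr$temperatures == p0$t_surr_C))  # no source, no heating
  # steady state: dT = (eta I (1 - 10^-Abs) + Q) / hS
  p <- pars()
  tr2 <- simulate_heating(p, eta = 0.15, on_s = 15 * p$tau_c_s, off_s = 100)
  dT_ss <- (0.15 * p$I_mW * (1 - 10^(-p$abs_lambda)) + p$q_dis_mW) / p$hS_mW_C
  expect_equal(max(tr2$temperatures), p$t_surr_C + dT_ss, tolerance = 1e-6)
  # cooling is a single exponential from T_max
  seg <- cooling_segment(tr2)
  expect_equal(seg$temperatures,
               p$t_surr_C + (seg$T_max - p$t_surr_C) * exp(-seg$times / p$tau_c_s),
               tolerance = 1e-9)
})

test_that("theta transform maps the cooling curve onto -t/tau", {
  p <- pars()
  tr <- simulate_heating(p, 0.15, on_s = 15 * p$tau_c_s, off_s = 540)
  th <- theta_transform(tr, lag_s = 0, theta_min = 0)
  expect_equal(th$ln_theta[1], 0)                      # t = 0: T = T_max
  expect_equal(th$ln_theta, -th$t_s / 180, tolerance = 1e-9)
  # theta = 1/e corresponds to ln theta = -1
  i <- which.min(abs(th$t_s - 180))
  expect_equal(th$ln_theta[i], -1, tolerance = 1e-6)
  # all samples at ambient -> degenerate
  flat <- temperature_trace(0:10, rep(25, 11), c(rep(1L, 5), rep(0L, 6)))
  expect_error(theta_transform(flat), "degenerate|usable")
})

test_that("tau_c fit recovers the generating constant exactly and scales", {
  p <- pars()
  tr <- simulate_heating(p, 0.15, on_s = 15 * p$tau_c_s, off_s = 3 * p$tau_c_s)
  fit <- fit_tau_c(theta_transform(tr))
  expect_equal(fit$tau_c_s, 180, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)
  p2 <- lumped_thermal_params(tau_c_s = 360, q_dis_mW = 10, I_mW = 2000)
  tr2 <- simulate_heating(p2, 0.15, on_s = 15 * 360, off_s = 3 * 360)
  expect_equal(fit_tau_c(theta_transform(tr2))$tau_c_s, 360, tolerance = 1e-6)
  expect_error(fit_tau_c(data.frame(t_s = 1:2, ln_theta = -(1:2))), "3")
})

test_that("hS follows m Cp / tau_c in mW per degC", {
  expect_equal(compute_hS(1, 4.18, 209), 20)
  expect_equal(compute_hS(1, 4.18, 418), 10)
  expect_error(compute_hS(1, 4.18, 0), "positive")
})

test_that("efficiency formula matches hand arithmetic and boundaries", {
  r <- compute_pce(hS_mW_C = 2, t_max_C = 45, t_surr_C = 25, q_dis_mW = 5,
                   I_mW = 300, abs_lambda = 1)
  expect_equal(r$eta, 35 / 270, tolerance = 1e-12)
  expect_false(r$clamped)
  # Q_dis exactly balancing the temperature rise gives eta = 0
  expect_equal(compute_pce(2, 45, 25, q_dis_mW = 40, I_mW = 300,
                           abs_lambda = 1)$eta, 0)
  expect_error(compute_pce(2, 45, 25, 5, 300, abs_lambda = 0), "absorbed")
  expect_warning(compute_pce(2, 45, 25, q_dis_mW = -500, I_mW = 300,
                             abs_lambda = 1), "clamped")
})

test_that("noiseless round trip recovers eta, tau_c and hS", {
  p <- pars()
  for (eta_true in c(0.05, 0.15, 0.3)) {
    tr <- simulate_heating(p, eta_true, on_s = 12 * p$tau_c_s,
                           off_s = 3 * p$tau_c_s)
    est <- estimate_pce(tr, I_mW = p$I_mW, abs_lambda = p$abs_lambda,
                        q_dis_mW = p$q_dis_mW)
    expect_equal(est$eta, eta_true, tolerance = 1e-3)
    expect_equal(est$diagnostics$tau_c_s, p$tau_c_s, tolerance = 1e-3)
    expect_equal(est$hS_mW_C, p$hS_mW_C, tolerance = 1e-3)
  }
})

test_that("estimate is invariant to time resampling and monotone in T_max", {
  p <- pars()
  tr1 <- simulate_heating(p, 0.15, on_s = 12 * p$tau_c_s,
                          off_s = 3 * p$tau_c_s, dt_s = 1)
  tr2 <- simulate_heating(p, 0.15, on_s = 12 * p$tau_c_s,
                          off_s = 3 * p$tau_c_s, dt_s = 0.5)
  e1 <- estimate_pce(tr1, I_mW = p$I_mW, abs_lambda = 1, q_dis_mW = 10)$eta
  e2 <- estimate_pce(tr2, I_mW = p$I_mW, abs_lambda = 1, q_dis_mW = 10)$eta
  expect_equal(e1, e2, tolerance = 1e-4)
  # larger T_max at fixed everything else -> larger eta
  etas <- vapply(c(40, 45, 50), function(tm)
    compute_pce(2, tm, 25, 5, 300, 1)$eta, numeric(1))
  expect_true(all(diff(etas) > 0))
})

test_that("blank-cell dissipation is recovered from a blank trace", {
  blank <- lumped_thermal_params(tau_c_s = 180, q_dis_mW = 25, I_mW = 2000)
  tr <- simulate_heating(blank, eta = 0, on_s = 12 * 180, off_s = 3 * 180)
  expect_equal(estimate_q_dis(tr), 25, tolerance = 1e-3)
})
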