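cab10 <- cable_params(tau = 10, lambda = 1, r_outer = 0.44)

test_that("spectral surds satisfy their defining identities across frequencies", {
  for (tau in c(5, 10, 20)) {
    cab <- cable_params(tau = tau)
    omega <- omega_rad_ms(c(0, 0.25, 1, 4, 10, 16, 100))
    pq <- cable_pq(omega, cab)
    expect_equal(pq$p^2 - pq$q^2, rep(1, length(omega)), tolerance = 1e-12)
    expect_equal(2 * pq$p * pq$q, omega * tau, tolerance = 1e-12)
    expect_true(all(pq$p >= pq$q), info = "p >= q")
    expect_true(all(pq$q >= 0))
  }
})

test_that("spectral surds reach their limiting values", {
  pq0 <- cable_pq(0, cab10)
  expect_equal(pq0$p, 1)
  expect_equal(pq0$q, 0)
  # frozen direct evaluation at f = 10 Hz, tau = 10 ms (omega*tau = 0.6283)
  pq <- cable_pq(omega_rad_ms(10), cab10)
  expect_equal(pq$p, 1.0442724, tolerance = 1e-6)
  expect_equal(pq$q, 0.3008403, tolerance = 1e-6)
  # large-beta asymptote: p ~ q ~ sqrt(beta / 2)
  om <- omega_rad_ms(1e6)
  pqL <- cable_pq(om, cab10)
  expect_equal(pqL$p, sqrt(om * 10 / 2), tolerance = 1e-3)
  expect_equal(pqL$q, sqrt(om * 10 / 2), tolerance = 1e-3)
  expect_error(cable_pq(NaN, cab10), "finite")
})

test_that("band response degenerates and simplifies as expected", {
  omega <- omega_rad_ms(10)
  t <- seq(0, 200, by = 0.1)
  degen <- cable_params(tau = 10, r_inner = 0.3, r_outer = 0.3)
  expect_warning(v <- band_response(t, degen, omega), "degenerate")
  expect_equal(v, rep(0, length(t)))
  # distal edge at infinity: response reduces to kappa * F(0, t)
  far <- cable_params(tau = 10, r_inner = 0, r_outer = 500)
  pq <- cable_pq(omega, far)
  expected <- cos(omega * t - atan2(pq$q, pq$p)) / sqrt(pq$p^2 + pq$q^2)
  expect_equal(band_response(t, far, omega), expected, tolerance = 1e-10)
})

test_that("point-stimulation phase shift is linear in distance and equals q at one length constant", {
  expect_equal(phase_shift_point(10, 0, cab10), 0)
  phi1 <- phase_shift_point(10, 0.7, cab10, wrap = FALSE)
  phi2 <- phase_shift_point(10, 1.4, cab10, wrap = FALSE)
  expect_equal(phi2, 2 * phi1, tolerance = 1e-12)
  pq <- cable_pq(omega_rad_ms(10), cab10)
  expect_equal(phase_shift_point(10, 1, cab10), pq$q, tolerance = 1e-12)
  # unwrapped point shift at 10 lambda exceeds the band-stimulation bound
  expect_gt(phase_shift_point(10, 10, cab10, wrap = FALSE),
            atan2(pq$q, pq$p))
})

test_that("band-stimulation phase shift is bounded, monotone and has the analytic limits", {
  pq <- cable_pq(omega_rad_ms(10), cab10)
  bound <- atan2(pq$q, pq$p)
  expect_equal(phase_shift_band(10, 0, cab10), 0)
  expect_equal(phase_shift_band(10, 1e4, cab10), bound, tolerance = 1e-9)
  Rs <- seq(0, 5, by = 0.05)
  phis <- phase_shift_band(10, Rs, cab10)
  expect_true(all(phis >= 0 & phis <= bound + 1e-12))
  expect_true(all(diff(phis) >= -1e-12), info = "monotone non-decreasing in R")
})

test_that("CCF stationarity equation reduces to the point and band closed forms", {
  for (f in c(1, 4, 10, 16)) {
    # r = 0: reduction to the soma-anchored band formula
    cab <- cable_params(tau = 10, r_inner = 0, r_outer = 0.44)
    expect_equal(solve_ccf_delay(f, cab)$phi_rad,
                 phase_shift_band(f, 0.44, cab), tolerance = 1e-6)
    # narrow band at distance R: reduction to the point formula
    thin <- cable_params(tau = 10, r_inner = 0.6, r_outer = 0.6 + 1e-3)
    expect_equal(solve_ccf_delay(f, thin)$phi_rad,
                 phase_shift_point(f, 0.6 + 5e-4, thin), tolerance = 1e-3)
  }
})

test_that("CCF stationarity solution matches a brute-force CCF peak for a general band", {
  cab <- cable_params(tau = 10, r_inner = 0.2, r_outer = 0.6)
  f <- 10
  t <- seq(0, 400, by = 0.05)
  v <- band_response(t, cab, omega_rad_ms(f))
  expect_equal(solve_ccf_delay(f, cab)$phi_rad,
               brute_ccf_phase(t, v, f), tolerance = 1e-4)
})

test_that("somatic phase correction spans [0, pi/2) and matches direct arithmetic", {
  expect_equal(soma_phase(0, 10), 0)
  expect_equal(soma_phase(16, 10), atan(2 * pi * 16 * 0.010),
               tolerance = 1e-12)
  expect_lt(soma_phase(1e6, 10), pi / 2)
  f <- seq(0.25, 16, by = 0.25)
  expect_true(all(diff(soma_phase(f, 10)) > 0))
})

test_that("ccf_peak recovers known shifts to sub-sample precision", {
  f <- 10
  omega <- omega_rad_ms(f)
  t <- seq(0, 500, by = 0.5)
  stim <- data.frame(time_ms = t, value = cos(omega * t))
  expect_equal(ccf_peak(stim, f)$delta_ms, 0, tolerance = 1e-6)
  shifted <- data.frame(time_ms = t, value = cos(omega * t - 0.3))
  res <- ccf_peak(shifted, f)
  expect_equal(res$phi_rad, 0.3, tolerance = 1e-3)
  expect_equal(res$delta_ms, 0.3 / omega, tolerance = 0.02)
  # reference phase taken from a non-zero-phase stimulus
  stim2 <- data.frame(time_ms = t, value = cos(omega * t - 0.2))
  expect_equal(ccf_peak(shifted, f, stim = stim2)$phi_rad, 0.1,
               tolerance = 1e-3)
})

test_that("ccf_peak tolerates noise at realistic SNR", {
  set.seed(42)
  f <- 10
  omega <- omega_rad_ms(f)
  cab <- cable_params(tau = 10, r_outer = 0.44)
  truth <- phase_shift_band(f, 0.44, cab)
  t <- seq(0, 3000, by = 0.5)
  v <- cos(omega * t - truth)
  resp <- data.frame(time_ms = t, value = v + rnorm(length(t), 0, 0.1))
  expect_lt(abs(ccf_peak(resp, f)$phi_rad - truth), 0.02)
})

test_that("ccf_peak rejects unusable traces", {
  t <- seq(0, 50, by = 0.5)
  expect_error(ccf_peak(data.frame(time_ms = t, value = cos(t)), f = 1),
               "at least one full period")
  t2 <- seq(0, 500, by = 0.5)
  expect_error(ccf_peak(data.frame(time_ms = t2, value = rep(1, length(t2))),
                        f = 10), "flat")
  tb <- c(seq(0, 100, by = 0.5), 101.3)
  expect_error(ccf_peak(data.frame(time_ms = tb, value = cos(tb)), f = 50),
               "uniform")
})

test_that("electrotonic fit recovers parameters exactly from noiseless phases", {
  tau <- 10; rho <- 0.4
  cab <- cable_params(tau = tau, lambda = 1, r_outer = rho)
  f <- c(6, 8, 10, 12, 14, 16)
  ph <- (phase_shift_band(f, rho, cab) + soma_phase(f, tau)) / (2 * pi)
  fit <- fit_electrotonic(phase_freq_data(f, ph))
  expect_lt(abs(fit$tau - tau), 1e-3)
  expect_lt(abs(fit$rho - rho), 1e-4)
})

test_that("electrotonic fit recovers parameters within 10% at realistic trace noise", {
  # noise enters where it does in the experiment: on the recorded traces,
  # then propagates through CCF phase extraction into the fit
  # the fit targets the phase curve averaged over 6 cells, as in the study
  tau <- 10; rho <- 0.4
  cab <- cable_params(tau = tau, lambda = 1, r_outer = rho)
  f <- c(6, 8, 10, 12, 14, 16)
  set.seed(7)
  est <- t(sapply(1:15, function(i) {
    ph <- rowMeans(sapply(1:6, function(cell)
      sweep_phases(gen_cable_sweep(f, cab, noise_sd = 0.1,
                                   duration_ms = 3000,
                                   fs_khz = 2))$phase_cycles))
    fit <- fit_electrotonic(phase_freq_data(f, ph))
    c(fit$tau, fit$rho)
  }))
  expect_lt(sqrt(mean((est[, 1] - tau)^2)) / tau, 0.10)
  expect_lt(sqrt(mean((est[, 2] - rho)^2)) / rho, 0.10)
  # the membrane time constant stays identifiable even from bare phases
  # with 0.01-cycle errors (rho does not: its signal spans ~0.01 cycles)
  truth <- (phase_shift_band(f, rho, cab) + soma_phase(f, tau)) / (2 * pi)
  taus <- replicate(50, fit_electrotonic(
    phase_freq_data(f, truth + rnorm(6, 0, 0.01)))$tau)
  expect_lt(abs(stats::median(taus) - tau) / tau, 0.10)
})

test_that("characteristic length follows from rho and the stimulation radius", {
  cab <- cable_params(tau = 9, lambda = 1, r_outer = 0.05)
  f <- c(6, 8, 10, 12, 14, 16)
  ph <- (phase_shift_band(f, 0.05, cab) + soma_phase(f, 9)) / (2 * pi)
  fit <- fit_electrotonic(phase_freq_data(f, ph), stim_radius_known = 65)
  expect_equal(fit$lambda, 65 / fit$rho, tolerance = 1e-12)
  expect_equal(fit$lambda, 1300, tolerance = 1e-2)
})

test_that("electrotonic fit demands enough in-range frequencies", {
  d <- phase_freq_data(c(1, 2, 8), c(0.01, 0.02, 0.1))
  expect_error(fit_electrotonic(d), "at least 3 frequencies")
})
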