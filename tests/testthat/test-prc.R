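test_that("pulses are assigned to the correct ISI and phase bin", {
  sp <- spike_train(c(0, 100), window = c(0, 100))
  b <- bin_pulses(sp, pulse_train(1), n_bins = 50)
  expect_equal(b$counts[1, 1], 1L)        # phase 0.01 -> bin 1
  expect_equal(sum(b$counts), 1L)
  b2 <- bin_pulses(sp, pulse_train(99.9), n_bins = 50)
  expect_equal(b2$counts[1, 50], 1L)
  # bin centers
  expect_equal(b$phi, (1:50 - 0.5) / 50)
})

test_that("a pulse at a spike time opens the following ISI", {
  sp <- spike_train(c(0, 100, 200), window = c(0, 200))
  b <- bin_pulses(sp, pulse_train(100))
  expect_equal(b$counts[2, 1], 1L)
  expect_equal(sum(b$counts[1, ]), 0L)
  # pulses outside [first, last) are dropped and counted
  b3 <- bin_pulses(sp, pulse_train(c(-5, 50, 200, 250)))
  expect_equal(sum(b3$counts), 1L)
  expect_equal(b3$n_dropped, 3L)
})

test_that("binned counts respect their bookkeeping invariants", {
  set.seed(3)
  sp <- gen_pacemaker(10000, f0 = 7, jitter_sd = 0.02, seed = 3)
  pu <- gen_barrage(10000, mean_ipi_ms = 6, seed = 4)
  b <- bin_pulses(sp, pu)
  expect_true(all(b$counts >= 0))
  expect_equal(sum(b$counts) + b$n_dropped, length(pu$onsets))
  expect_lt(abs(mean(b$delta)), 1e-12)
  # Poisson count sanity: total binned pulses ~ covered time / mean IPI
  covered <- sum(b$isis)
  expected <- covered / 6
  expect_lt(abs(sum(b$counts) - expected), 3 * sqrt(expected))
})

test_that("regression PRC solves a constructed problem with a known answer", {
  set.seed(5)
  n <- 400
  counts <- matrix(rpois(n * 50, 2), n, 50)
  isis <- 100 - 1 * counts[, 25]   # each bin-25 pulse shortens the ISI by 1 ms
  b <- structure(list(counts = counts, delta = counts - mean(counts),
                      isis = isis, phi = (1:50 - 0.5) / 50, n_dropped = 0L),
                 class = "binned_pulses")
  est <- estimate_prc(b)
  # the exact algebra: ISI = (100 - mean(counts)) - delta[,25], so the
  # intercept is 100 minus the grand-mean pulse count and b_25 = -1
  expect_equal(est$mean_isi_ms, 100 - mean(counts), tolerance = 1e-8)
  expect_equal(est$z[25], 1 / est$mean_isi_ms, tolerance = 1e-8)
  expect_equal(est$z[25], 0.01, tolerance = 0.05)
  expect_true(all(abs(est$z[-25]) < 1e-8))
  # the regression itself is exactly linear in the effect size: doubling it
  # doubles the raw coefficient z * Tbar; the phase-unit value follows to
  # first order
  b2 <- b; b2$isis <- 100 - 2 * counts[, 25]
  est2 <- estimate_prc(b2)
  expect_equal(est2$z[25] * est2$mean_isi_ms,
               2 * est$z[25] * est$mean_isi_ms, tolerance = 1e-7)
  expect_equal(est2$z[25], 2 * est$z[25], tolerance = 0.05)
})

test_that("pulses with no effect on ISIs give a null PRC", {
  set.seed(6)
  n <- 500
  counts <- matrix(rpois(n * 50, 2), n, 50)
  isis <- rnorm(n, 140, 3)        # independent of the pulses
  b <- structure(list(counts = counts, delta = counts - mean(counts),
                      isis = isis, phi = (1:50 - 0.5) / 50, n_dropped = 0L),
                 class = "binned_pulses")
  est <- estimate_prc(b)
  # ~0.3% of coefficients expected beyond 3 SE; allow a small margin
  expect_lt(mean(abs(est$z) > 3 * est$se), 0.08)
})

test_that("empty phase bins are dropped from the regression and reported", {
  set.seed(8)
  n <- 300
  counts <- matrix(rpois(n * 50, 2), n, 50)
  counts[, 7] <- 0L
  isis <- 100 - counts[, 25]
  b <- structure(list(counts = counts, delta = counts - mean(counts),
                      isis = isis, phi = (1:50 - 0.5) / 50, n_dropped = 0L),
                 class = "binned_pulses")
  expect_warning(est <- estimate_prc(b), "never received")
  expect_true(is.na(est$z[7]))
  expect_equal(est$z[25], 1 / est$mean_isi_ms, tolerance = 1e-7)
})

test_that("triangle fit recovers exact triangle samples to high precision", {
  phi <- (1:50 - 0.5) / 50
  truth <- triangular_prc(theta = 0.763, amp = 0.0179, offset = -0.0053)
  fit <- fit_triangle(predict(truth, phi), phi = phi)
  expect_equal(fit$theta, 0.763, tolerance = 1e-6)
  expect_equal(fit$amp, 0.0179, tolerance = 1e-6)
  expect_equal(fit$offset, -0.0053, tolerance = 1e-6)
  # symmetric tent
  sym <- fit_triangle(predict(triangular_prc(0.5), phi), phi = phi)
  expect_equal(sym$theta, 0.5, tolerance = 1e-6)
  # zero-ends constraint pins the offset
  fz <- fit_triangle(predict(triangular_prc(0.8, amp = 0.01), phi), phi = phi,
                     force_zero_ends = TRUE)
  expect_equal(fz$offset, 0)
  expect_equal(fz$theta, 0.8, tolerance = 1e-6)
  expect_error(fit_triangle(rep(0.5, 50), phi = phi), "flat")
})

test_that("triangle fit peak location is unbiased under noise", {
  phi <- (1:50 - 0.5) / 50
  truth <- predict(triangular_prc(0.763, amp = 0.0179), phi)
  set.seed(9)
  thetas <- replicate(60, fit_triangle(truth + rnorm(50, 0, 0.1 * 0.0179),
                                       phi = phi)$theta)
  expect_lt(abs(mean(thetas) - 0.763), 0.01)
})

test_that("triangle Fourier coefficients obey the series definition", {
  expect_equal(triangle_fourier(0.7, 0), 0.5 + 0i)
  # conjugate symmetry of a real PRC
  for (theta in c(0.25, 0.5, 0.763, 0.9)) {
    k <- 1:5
    expect_equal(triangle_fourier(theta, -k), Conj(triangle_fourier(theta, k)))
  }
  # against the numeric Fourier integral of the tent function
  expect_equal(triangle_fourier(0.5, 1), numeric_triangle_fourier(0.5, 1),
               tolerance = 1e-9)
  expect_equal(triangle_fourier(0.5, 1), -2 / pi^2 + 0i, tolerance = 1e-9)
  expect_equal(triangle_fourier(0.763, 3), numeric_triangle_fourier(0.763, 3),
               tolerance = 1e-9)
  # accepts a triangular_prc and reads its peak
  expect_equal(triangle_fourier(triangular_prc(0.763), 2),
               triangle_fourier(0.763, 2))
})

test_that("truncated Fourier series reconstructs the unit triangle", {
  phi <- seq(0, 1, length.out = 1000)
  for (theta in c(0.25, 0.763)) {
    k <- -100:100
    zk <- triangle_fourier(theta, k)
    rec <- Re(exp(2i * pi * outer(phi, k)) %*% zk)
    expect_lt(max(abs(rec - predict(triangular_prc(theta), phi))), 0.01)
  }
})

test_that("ChR2 kernel fit recovers generating kinetics", {
  kin <- chr2_kinetics(amp = -20, tau_rise = 1.5, tau_decay = 5.1)
  t <- seq(0, 40, by = 0.05)
  fit <- fit_chr2_kernel(data.frame(time_ms = t, value = chr2_kernel(t, kin)))
  expect_equal(fit$tau_rise, 1.5, tolerance = 1e-6)
  expect_equal(fit$tau_decay, 5.1, tolerance = 1e-6)
  expect_equal(fit$amp, -20, tolerance = 1e-5)
  expect_equal(chr2_kernel(0, kin), 0)
})

test_that("ChR2 kernel extremum matches the closed form", {
  kin <- chr2_kinetics(amp = -1, tau_rise = 3.6, tau_decay = 4.9)
  tstar <- chr2_peak_time(kin)
  expect_equal(tstar, 3.6 * 4.9 / (4.9 - 3.6) * log(4.9 / 3.6),
               tolerance = 1e-12)
  t <- seq(0, 60, by = 1e-3)
  expect_equal(t[which.max(abs(chr2_kernel(t, kin)))], tstar,
               tolerance = 1e-2)
})

test_that("ChR2 kinetics relabel swapped time constants without changing the curve", {
  a <- chr2_kinetics(amp = 2, tau_rise = 5, tau_decay = 1.5)
  b <- chr2_kinetics(amp = -2, tau_rise = 1.5, tau_decay = 5)
  t <- seq(0, 30, by = 0.1)
  expect_equal(chr2_kernel(t, a), chr2_kernel(t, b))
  expect_lt(a$tau_rise, a$tau_decay)
})

test_that("PRC estimation pipeline recovers the generating peak phase", {
  # single-condition recovery; the multi-theta seeded study runs with the
  # acceptance checks
  pulses <- gen_barrage(3e5, mean_ipi_ms = 6, seed = 21)
  sp <- gen_pacemaker(3e5, f0 = 7, prc = triangular_prc(0.8),
                      stimulus = pulses, a_eff = 0.02, jitter_sd = 0.02,
                      seed = 22)
  est <- estimate_prc(bin_pulses(sp, pulses))
  tri <- fit_triangle(est, force_zero_ends = TRUE)
  expect_lt(abs(tri$theta - 0.8), 0.05)
  expect_lt(abs(tri$amp - 0.02), 0.01)
})
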