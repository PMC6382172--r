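# Independent oracles used across tests.

# Brute-force CCF peak: directly maximize the time-average of
# cos(omega*(t - Delta)) * resp(t) over Delta, by a coarse scan plus
# golden-section refinement. Independent of ccf_peak()'s lag-grid /
# parabolic-interpolation path.
brute_ccf_phase <- function(time_ms, value, f) {
  omega <- 2 * pi * f / 1000
  period <- 1000 / f
  dt <- time_ms[2] - time_ms[1]
  n_per <- floor((time_ms[length(time_ms)] - time_ms[1]) / period)
  n_use <- max(which(time_ms - time_ms[1] < n_per * period))
  tt <- time_ms[seq_len(n_use)]
  vv <- value[seq_len(n_use)]
  cc <- function(d) mean(cos(omega * (tt - d)) * vv)
  grid <- seq(0, period, length.out = 1025)[-1025]
  i <- which.max(vapply(grid, cc, numeric(1)))
  lo <- grid[if (i == 1) 1 else i - 1]
  hi <- grid[min(i + 1, length(grid))]
  d <- stats::optimize(cc, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
  (omega * d) %% (2 * pi)
}

# Numeric Fourier coefficient of the zero-offset unit triangle,
# Zhat_k = integral_0^1 Z(phi) exp(-2 pi i k phi) dphi, by quadrature.
numeric_triangle_fourier <- function(theta, k) {
  tri <- function(p) ifelse(p <= theta, p / theta, (1 - p) / (1 - theta))
  re <- stats::integrate(function(p) tri(p) * cos(2 * pi * k * p), 0, 1,
                         subdivisions = 2000, rel.tol = 1e-12)$value
  im <- stats::integrate(function(p) tri(p) * sin(2 * pi * k * p), 0, 1,
                         subdivisions = 2000, rel.tol = 1e-12)$value
  complex(real = re, imaginary = -im)
}

# Exactly periodic pacemaker spike times (no jitter, no stimulus).
regular_train <- function(f0 = 7, duration_ms = 10000, t_first = 0) {
  t0 <- 1000 / f0
  spike_train(seq(t_first, duration_ms, by = t0),
              window = c(0, duration_ms))
}
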