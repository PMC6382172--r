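#' Effective phase of each spike relative to a periodic stimulus
#'
#' The effective phase of a spike is its position inside the current cycle
#' of the rhythmic stimulus, `psi = frac(f * (t - t_stim_start) / 1000)` in
#' cycles. Under the drive convention used throughout this package
#' (`-A * cos(2*pi*(f*t + psi))` multiplying the PRC), the depolarizing peak
#' of the drive sits at effective phase 0.5.
#'
#' @param spikes a [spike_train()] or numeric spike times in ms.
#' @param f stimulus frequency in Hz.
#' @param t_stim_start stimulus onset time in ms (default 0).
#' @return Numeric vector of phases in `[0, 1)`.
#' @export
effective_phases <- function(spikes, f, t_stim_start = 0) {
  t <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  stopifnot(is.numeric(t), f > 0)
  (f * (t - t_stim_start) / 1000) %% 1
}

#' Perturbed periods paired with effective phases
#'
#' For each spike (except the last), pairs the effective phase `psi_n` at
#' which it occurred with the duration `T_p,n = t_{n+1} - t_n` of the
#' following (perturbed) period.
#'
#' @inheritParams effective_phases
#' @return A data frame with columns `psi` (cycles) and `tp_ms`.
#' @export
perturbed_periods <- function(spikes, f, t_stim_start = 0) {
  t <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  if (length(t) < 2L) stop("need at least 2 spikes to measure a period")
  psi <- effective_phases(t, f, t_stim_start)
  data.frame(psi = psi[-length(psi)], tp_ms = diff(t))
}

#' Fit a low-order Fourier curve to perturbed-period measurements
#'
#' Least-squares fit of `T_p(psi) = a0 + sum_{m=1..modes} (a_m *
#' cos(2*pi*m*psi) + b_m * sin(2*pi*m*psi))` (default 3 modes) to the
#' scatter of perturbed periods versus effective phase. A session in which
#' the pacemaker is phase locked visits only a narrow band of effective
#' phases and cannot constrain the curve; if the largest circular gap in
#' phase coverage exceeds `max_gap` the fit aborts with a "locked session"
#' error.
#'
#' @param pairs a data frame with columns `psi` and `tp_ms`, as returned by
#'   [perturbed_periods()].
#' @param modes number of Fourier modes (default 3).
#' @param max_gap largest tolerated circular gap in `psi` coverage (cycles).
#' @return An object of class `"tp_fit"`: list with `coefficients`, the
#'   fitted periodic function `tp_fn(psi)` (ms), and `modes`.
#' @export
fit_tp_curve <- function(pairs, modes = 3L, max_gap = 0.25) {
  stopifnot(is.data.frame(pairs), all(c("psi", "tp_ms") %in% names(pairs)),
            modes >= 1L)
  psi <- pairs$psi %% 1
  tp <- pairs$tp_ms
  if (length(psi) < 2L * modes + 1L)
    stop("too few (psi, Tp) pairs for the requested number of modes")
  s <- sort(psi)
  gaps <- diff(c(s, s[1] + 1))
  if (max(gaps) > max_gap)
    stop(sprintf(paste0("locked session: effective phases leave a circular gap ",
                        "of %.2f cycles (> %.2f); a return-map curve cannot be ",
                        "fit to a phase-locked recording"),
                 max(gaps), max_gap))
  X <- do.call(cbind, c(list(rep(1, length(psi))),
                        lapply(seq_len(modes), function(m)
                          cbind(cos(2 * pi * m * psi),
                                sin(2 * pi * m * psi)))))
  colnames(X) <- c("a0", as.vector(rbind(paste0("a", seq_len(modes)),
                                         paste0("b", seq_len(modes)))))
  cf <- stats::lm.fit(X, tp)$coefficients
  tp_fn <- local({
    cf <- cf; modes <- modes
    function(psi) {
      p <- psi %% 1
      out <- rep(cf[["a0"]], length(p))
      for (m in seq_len(modes))
        out <- out + cf[[paste0("a", m)]] * cos(2 * pi * m * p) +
          cf[[paste0("b", m)]] * sin(2 * pi * m * p)
      out
    }
  })
  structure(list(coefficients = cf, tp_fn = tp_fn, modes = modes,
                 n = length(psi)),
            class = "tp_fit")
}

#' @export
print.tp_fit <- function(x, ...) {
  cat(sprintf("Perturbed-period curve: %d Fourier modes fit to %d pairs\n",
              x$modes, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Simulate the perturbed period of a driven phase oscillator
#'
#' Integrates the phase-evolution equation
#' `dphi/dt = f0 - A * cos(2*pi*(f*t + psi)) * Z(phi)`
#' from intrinsic phase `phi = 0` at the spike time (`t = 0`, occurring at
#' effective stimulus phase `psi`) until `phi` reaches 1, and returns the
#' crossing time: the perturbed period `T_p(psi)`. Equivalently the
#' phase change bookkeeping reads `T_p = T_0 * (1 - dphi)` with
#' `dphi = 1 - T_p * f0`. Integration is classical fixed-step 4th-order
#' Runge-Kutta with `dt = T_0 / 10^4`; the crossing of 1 is located by
#' linear interpolation of the final step.
#'
#' @param prc the pacemaker's PRC: a [triangular_prc()] (use zero offset for
#'   the canonical analysis) or any function of phase.
#' @param f stimulus frequency in Hz.
#' @param f0 natural firing rate in spikes/s.
#' @param A drive amplitude, the dimensionless product multiplying the unit
#'   PRC in the phase equation (units of `f0`).
#' @param psi effective phase(s) of the reference spike, in `[0, 1)`
#'   (vectorized).
#' @param dt integration step in seconds (default `1 / (10^4 * f0)`).
#' @return Perturbed period(s) `T_p` in ms.
#' @examples
#' simulate_tp(triangular_prc(0.9), f = 7, f0 = 7, A = 0, psi = 0.3)  # = 1000/7
#' @export
simulate_tp <- function(prc, f, f0, A, psi, dt = 1 / (1e4 * f0)) {
  stopifnot(f > 0, f0 > 0, all(psi >= 0), all(psi < 1))
  zfun <- if (is.function(prc)) prc else function(p) predict(prc, p)
  # all initial phases are integrated in lockstep on a shared time grid
  n <- length(psi)
  phi <- numeric(n)
  tp <- rep(NA_real_, n)
  live <- rep(TRUE, n)
  t <- 0
  tmax <- 10 / f0
  deriv <- function(t, phi, ps) f0 - A * cos(2 * pi * (f * t + ps)) * zfun(phi)
  while (any(live)) {
    ps <- psi[live]
    ph <- phi[live]
    k1 <- deriv(t, ph, ps)
    k2 <- deriv(t + dt / 2, ph + dt / 2 * k1, ps)
    k3 <- deriv(t + dt / 2, ph + dt / 2 * k2, ps)
    k4 <- deriv(t + dt, ph + dt * k3, ps)
    ph_new <- ph + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    crossed <- ph_new >= 1
    if (any(crossed)) {
      idx <- which(live)[crossed]
      tp[idx] <- 1000 * (t + dt * (1 - ph[crossed]) /
                           (ph_new[crossed] - ph[crossed]))
      live[idx] <- FALSE
    }
    phi[live] <- ph_new[!crossed]
    t <- t + dt
    if (t > tmax && any(live))
      stop(sprintf(paste0("intrinsic phase failed to reach 1 within 10 ",
                          "natural periods (psi = %.3f): the drive cancels ",
                          "the pacemaking"), psi[which(live)[1]]))
  }
  tp
}

#' Effective-phase return map
#'
#' Builds the iterative map `psi_{n+1} = (psi_n + T_p(psi_n) / T) mod 1`
#' relating the effective phase of one spike to that of the next under a
#' periodic stimulus of period `T`.
#'
#' @param tp_fn the perturbed-period curve `T_p(psi)` in ms: a function, a
#'   [fit_tp_curve()] object, or a single number (constant period).
#' @param T_ms stimulus period in ms.
#' @param provenance `"empirical"` or `"simulated"` tag.
#' @return An object of class `"phase_return_map"` with elements `T_ms`,
#'   `tp_fn` and `provenance`. Evaluate it with [map_eval()], iterate with
#'   [iterate_map()].
#' @export
build_map <- function(tp_fn, T_ms, provenance = "empirical") {
  stopifnot(T_ms > 0)
  fn <- if (inherits(tp_fn, "tp_fit")) tp_fn$tp_fn
  else if (is.function(tp_fn)) tp_fn
  else if (is.numeric(tp_fn) && length(tp_fn) == 1L)
    local({ v <- tp_fn; function(psi) rep(v, length(psi)) })
  else stop("'tp_fn' must be a function, tp_fit or a constant period")
  probe <- fn(seq(0, 1, length.out = 33)[-33])
  if (any(!is.finite(probe)) || any(probe <= 0))
    stop("T_p(psi) must be positive and finite over [0, 1)")
  structure(list(T_ms = T_ms, tp_fn = fn, provenance = provenance),
            class = "phase_return_map")
}

#' Evaluate a phase return map
#' @param map a [build_map()] object.
#' @param psi effective phases in cycles.
#' @param lift if `TRUE` return the unwrapped value `psi + T_p(psi)/T`
#'   without the modulus.
#' @return Next effective phase(s).
#' @export
map_eval <- function(map, psi, lift = FALSE) {
  stopifnot(inherits(map, "phase_return_map"))
  out <- psi + map$tp_fn(psi %% 1) / map$T_ms
  if (lift) out else out %% 1
}

#' Iterate a phase return map (cobweb orbit)
#' @param map a [build_map()] object.
#' @param psi0 initial effective phase.
#' @param n number of iterations.
#' @return Numeric vector of length `n + 1` with the orbit
#'   `psi_0, psi_1, ..., psi_n`.
#' @export
iterate_map <- function(map, psi0, n) {
  stopifnot(inherits(map, "phase_return_map"), n >= 1)
  out <- numeric(n + 1)
  out[1] <- psi0 %% 1
  for (i in seq_len(n)) out[i + 1] <- map_eval(map, out[i])
  out
}

#' @export
print.phase_return_map <- function(x, ...) {
  cat(sprintf("Effective-phase return map (%s), stimulus period %.4g ms\n",
              x$provenance, x$T_ms))
  fp <- find_fixed_points(x)
  if (nrow(fp) == 0) cat("  no fixed points (unlocked regime)\n")
  else for (i in seq_len(nrow(fp)))
    cat(sprintf("  fixed point psi* = %.4f, slope %.3f (%s)\n", fp$psi[i],
                fp$slope[i], if (fp$stable[i]) "stable" else "unstable"))
  invisible(x)
}

#' Cobweb plot of a phase return map
#'
#' @param x a [build_map()] object.
#' @param psi0 starting phase of the cobweb orbit.
#' @param n number of cobweb steps.
#' @param ... passed to [graphics::plot()].
#' @return The orbit, invisibly.
#' @export
plot.phase_return_map <- function(x, psi0 = 0.1, n = 30, ...) {
  g <- seq(0, 1, length.out = 513)
  graphics::plot(g, map_eval(x, g), type = "p", pch = ".", cex = 2,
                 xlab = expression(psi[n]), ylab = expression(psi[n + 1]),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, col = "blue")
  orb <- iterate_map(x, psi0, n)
  for (i in seq_len(n)) {
    graphics::segments(orb[i], orb[i], orb[i], orb[i + 1])
    graphics::segments(orb[i], orb[i + 1], orb[i + 1], orb[i + 1])
  }
  invisible(orb)
}

#' Fixed points and stability of a phase return map
#'
#' Finds all fixed points of the lifted map `g(psi) = psi + T_p(psi) / T`
#' in `[0, 1)`, i.e. roots of `T_p(psi) / T - m` for every reachable integer
#' `m`, by sampling 1024 points, bracketing sign changes and bisecting to
#' `1e-10`. The map slope at each root is evaluated by central difference
#' (`h = 1e-5`); a fixed point is stable when `|slope| < 1`, and the
#' pacemaker is then phase locked to the stimulus at that effective phase.
#'
#' @param map a [build_map()] object.
#' @return A data frame with columns `psi`, `slope`, `stable`. Zero rows
#'   means no locking (the map never meets the diagonal). An identity-like
#'   map, fixed everywhere, is flagged with attribute `degenerate = TRUE`.
#' @examples
#' m <- simulate_map(triangular_prc(0.9), f = 7, f0 = 7, A = 5)
#' find_fixed_points(m)
#' @export
find_fixed_points <- function(map) {
  stopifnot(inherits(map, "phase_return_map"))
  grid <- seq(0, 1, length.out = 1025L)
  h <- map$tp_fn(grid %% 1) / map$T_ms
  empty <- data.frame(psi = numeric(0), slope = numeric(0),
                      stable = logical(0))
  if (max(abs(h - round(h))) < 1e-12) {
    warning("degenerate map: every point is fixed (T_p is an exact multiple of T)")
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  ms <- seq(floor(min(h)), ceiling(max(h)))
  roots <- numeric(0)
  for (m in ms) {
    hm <- h - m
    for (i in seq_len(1024L)) {
      if (hm[i] == 0) roots <- c(roots, grid[i])
      else if (sign(hm[i]) != sign(hm[i + 1L])) {
        fn <- function(p) map$tp_fn(p %% 1) / map$T_ms - m
        roots <- c(roots, stats::uniroot(fn, c(grid[i], grid[i + 1L]),
                                         tol = 1e-10)$root)
      }
    }
  }
  roots <- sort(unique(roots %% 1))
  if (length(roots) == 0) return(empty)
  eps <- 1e-5
  slope <- vapply(roots, function(r)
    1 + (map$tp_fn((r + eps) %% 1) - map$tp_fn((r - eps) %% 1)) /
      (2 * eps) / map$T_ms, numeric(1))
  data.frame(psi = roots, slope = slope, stable = abs(slope) < 1)
}

#' Model-derived return map from a PRC
#'
#' Convenience wrapper: evaluates [simulate_tp()] on a grid of effective
#' phases (default 256), interpolates periodically with a cubic spline, and
#' builds the return map for stimulus period `T = 1000 / f` ms.
#'
#' @inheritParams simulate_tp
#' @param n_grid number of equally spaced `psi` values to simulate.
#' @return A [build_map()] object with provenance `"simulated"`.
#' @export
simulate_map <- function(prc, f, f0, A, n_grid = 256L,
                         dt = 1 / (1e4 * f0)) {
  psis <- seq(0, 1, length.out = n_grid + 1L)[-(n_grid + 1L)]
  tp <- simulate_tp(prc, f, f0, A, psis, dt = dt)
  fn <- stats::splinefun(c(psis, 1), c(tp, tp[1]), method = "periodic")
  build_map(function(p) fn(p %% 1), T_ms = 1000 / f,
            provenance = "simulated")
}

#' Predicted locking phase of a pacemaker under periodic drive
#'
#' Builds the model return map from a triangular PRC ([simulate_map()]) and
#' returns its stable fixed point(s): the effective phase(s) at which the
#' pacemaker's spikes lock to the stimulus.
#'
#' @param theta peak phase of the zero-offset unit triangular PRC.
#' @param A drive amplitude (dimensionless, multiplying the unit PRC).
#' @param f stimulus frequency in Hz.
#' @param f0 natural firing rate in spikes/s.
#' @param ... passed to [simulate_map()].
#' @return A data frame of stable fixed points (`psi`, `slope`, `stable`);
#'   zero rows when the drive does not lock the pacemaker.
#' @examples
#' \donttest{predict_locking(theta = 0.9, A = 5, f = 7, f0 = 7)}
#' @export
predict_locking <- function(theta, A, f, f0, ...) {
  fp <- find_fixed_points(simulate_map(triangular_prc(theta), f = f,
                                       f0 = f0, A = A, ...))
  fp[fp$stable, , drop = FALSE]
}

#' Circular variance vector of effective phases
#'
#' Mean of the unit phasors `exp(2*pi*i*psi)`. The amplitude (mean
#' resultant length, in `[0, 1]`) measures the strength of phase locking;
#' the argument, expressed in cycles, is the effective phase of
#' entrainment.
#'
#' @param phases effective phases in cycles.
#' @return An object of class `"circ_stat"`: list with `vector` (complex),
#'   `amplitude`, `phase` (cycles in `[0, 1)`) and `n`.
#' @examples
#' circular_stat(c(0.28, 0.3, 0.32))
#' @export
circular_stat <- function(phases) {
  stopifnot(is.numeric(phases), length(phases) >= 1L, all(is.finite(phases)))
  v <- mean(exp(2i * pi * phases))
  structure(list(vector = v, amplitude = Mod(v),
                 phase = (Arg(v) / (2 * pi)) %% 1, n = length(phases)),
            class = "circ_stat")
}

#' @export
print.circ_stat <- function(x, ...) {
  cat(sprintf("Circular variance vector: amplitude %.4f, phase %.4f cycles (n = %d)\n",
              x$amplitude, x$phase, x$n))
  invisible(x)
}

#' Bootstrap threshold for significant phase locking
#'
#' Generates `reps` surrogate series of `n` phases drawn uniformly on
#' `[0, 1)`, computes the circular-variance amplitude of each, and returns
#' the requested percentile. Amplitudes above the threshold indicate
#' entrainment beyond chance. For uniform phases the amplitude follows the
#' Rayleigh limit, giving the analytic approximation
#' `sqrt(-log(1 - percentile/100) / n)` (about 0.173 for `n = 100` at the
#' 95th percentile).
#'
#' @param n surrogate series length (default 100, the typical number of
#'   ISIs in an entrainment session).
#' @param reps number of surrogate series (default 10000).
#' @param percentile percentile of the amplitude distribution (default 95).
#' @param seed optional integer seed for reproducibility.
#' @return The amplitude threshold (scalar).
#' @export
bootstrap_threshold <- function(n = 100L, reps = 10000L, percentile = 95,
                                seed = NULL) {
  stopifnot(n >= 1L, reps >= 1L, percentile > 0, percentile < 100)
  if (n == 1L) return(1)
  if (!is.null(seed)) set.seed(seed)
  amps <- vapply(seq_len(reps),
                 function(i) Mod(mean(exp(2i * pi * stats::runif(n)))),
                 numeric(1))
  unname(stats::quantile(amps, percentile / 100))
}

# shorter-arc circular distance between phases in cycles
circ_dist <- function(a, b) abs(((a - b + 0.5) %% 1) - 0.5)

#' Bootstrap p-value for a displaced mean locking phase
#'
#' Tests whether the mean locking phase of a test condition could have
#' arisen from the distribution of locking vectors of a reference
#' condition. Reference phases are resampled with replacement with sampling
#' weight proportional to each vector's amplitude (strongly locked trials
#' carry more weight), in samples of size `n_test`; each resample's mean
#' phase is compared with the reference mean phase, and the p-value is the
#' fraction of resamples whose circular displacement (shorter arc, i.e.
#' two-sided) is at least that of the test condition.
#'
#' @param reference list of [circular_stat()] objects (or a data frame with
#'   columns `phase` and `amplitude`) for the reference condition.
#' @param test_mean_phase mean locking phase of the test condition, cycles.
#' @param n_test sample size of the test condition (default: number of
#'   reference vectors).
#' @param reps number of bootstrap resamples.
#' @param seed optional integer seed.
#' @return A list with `p`, `observed_shift` (cycles), `reference_mean`
#'   (cycles) and `reps`.
#' @export
bootstrap_phase_pvalue <- function(reference, test_mean_phase,
                                   n_test = NULL, reps = 10000L,
                                   seed = NULL) {
  if (is.data.frame(reference)) {
    phases <- reference$phase
    amps <- reference$amplitude
  } else {
    stopifnot(length(reference) >= 1L,
              all(vapply(reference, inherits, logical(1), "circ_stat")))
    phases <- vapply(reference, `[[`, numeric(1), "phase")
    amps <- vapply(reference, `[[`, numeric(1), "amplitude")
  }
  if (all(amps == 0)) stop("all reference amplitudes are zero; weights undefined")
  if (is.null(n_test)) n_test <- length(phases)
  if (!is.null(seed)) set.seed(seed)
  ref_mean <- (Arg(sum(amps * exp(2i * pi * phases))) / (2 * pi)) %% 1
  obs <- circ_dist(test_mean_phase, ref_mean)
  shifts <- vapply(seq_len(reps), function(i) {
    s <- sample(phases, n_test, replace = TRUE, prob = amps)
    m <- (Arg(mean(exp(2i * pi * s))) / (2 * pi)) %% 1
    circ_dist(m, ref_mean)
  }, numeric(1))
  list(p = mean(shifts >= obs), observed_shift = obs,
       reference_mean = ref_mean, reps = reps)
}
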