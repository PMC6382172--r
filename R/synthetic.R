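#' Bundle of synthetic-generation settings
#'
#' Collects the study conditions the generators emulate in one place:
#' a pacemaker at 7 spikes/s perturbed through a triangular PRC, Poisson
#' pulse barrages with exponential inter-pulse intervals, ChR2 photocurrent
#' kernels, session layout (3 s baseline + 9 s barrage, 25 sweeps), 20 kHz
#' sampling and mild period jitter. Individual generators take the same
#' quantities as explicit arguments with these defaults; the config is a
#' convenience container for scripted pipelines.
#'
#' @param seed integer seed; with the seed fixed every generator output is
#'   bit-identical.
#' @param f0 natural firing rate, spikes/s.
#' @param prc a [triangular_prc()] (zero offset) driving the pacemaker.
#' @param cable a [cable_params()] for the cable sweeps.
#' @param barrage list with `mean_ipi_ms` and `width_ms`.
#' @param chr2 a [chr2_kinetics()].
#' @param noise list with `jitter_sd` (period jitter, fraction of the
#'   natural period) and `trace_sd` (additive trace noise).
#' @param session list with `baseline_s`, `stim_s`, `sweeps`.
#' @param fs_khz sampling rate for generated traces, kHz.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, f0 = 7,
                             prc = triangular_prc(0.8),
                             cable = cable_params(tau = 10, lambda = 1,
                                                  r_outer = 0.44),
                             barrage = list(mean_ipi_ms = 6, width_ms = 0.5),
                             chr2 = chr2_kinetics(-1, 1.5, 5),
                             noise = list(jitter_sd = 0.02, trace_sd = 0.01),
                             session = list(baseline_s = 3, stim_s = 9,
                                            sweeps = 25),
                             fs_khz = 20) {
  stopifnot(f0 > 0, inherits(prc, "triangular_prc"),
            inherits(cable, "cable_params"), inherits(chr2, "chr2_kinetics"))
  structure(list(seed = as.integer(seed), f0 = f0, prc = prc, cable = cable,
                 barrage = barrage, chr2 = chr2, noise = noise,
                 session = session, fs_khz = fs_khz),
            class = "generator_config")
}

#' Generate a Poisson-like barrage of light pulses
#'
#' Draws inter-pulse intervals (onset to onset) i.i.d. as one pulse width
#' plus an exponential with mean `mean_ipi_ms - width_ms`: pulses never
#' overlap and the onset-to-onset mean equals `mean_ipi_ms` exactly, so
#' pulse counts match the nominal Poisson expectation
#' `duration / mean_ipi`.
#'
#' @param duration_ms barrage duration in ms (default one 9 s stimulation
#'   block).
#' @param mean_ipi_ms mean inter-pulse interval in ms (6 for the sparse and
#'   2.17 for the dense barrage condition).
#' @param width_ms pulse width in ms.
#' @param t_start onset of the first possible pulse (ms).
#' @param seed optional integer seed.
#' @return A [pulse_train()].
#' @export
gen_barrage <- function(duration_ms = 9000, mean_ipi_ms = 6, width_ms = 0.5,
                        t_start = 0, seed = NULL) {
  stopifnot(duration_ms > 0, mean_ipi_ms > width_ms)
  if (!is.null(seed)) set.seed(seed)
  n_guess <- ceiling(duration_ms / mean_ipi_ms * 1.5) + 20L
  draw <- function(n)
    width_ms + stats::rexp(n, rate = 1 / (mean_ipi_ms - width_ms))
  ipis <- draw(n_guess)
  on <- t_start + cumsum(ipis)
  while (on[length(on)] < t_start + duration_ms) {
    ipis <- draw(n_guess)
    on <- c(on, on[length(on)] + cumsum(ipis))
  }
  pulse_train(on[on < t_start + duration_ms], width = width_ms)
}

#' Synthesize a ChR2 photocurrent trace from a pulse train
#'
#' Linear superposition of the double-exponential kernel at every pulse
#' onset, sampled uniformly. Plotted-positive (inward) currents correspond
#' to a negative kernel amplitude, matching the printed kernel convention;
#' pass `kin` with `amp < 0` (the [generator_config()] default) for a
#' positive-going trace.
#'
#' @param pulses a [pulse_train()].
#' @param kin a [chr2_kinetics()].
#' @param fs_khz sampling rate in kHz (>= 10).
#' @param duration_ms trace length in ms (default: last pulse + 10 decay
#'   constants).
#' @param noise_sd additive Gaussian noise SD (same units as the kernel).
#' @param seed optional integer seed (used only when `noise_sd > 0`).
#' @return A data frame with columns `time_ms` and `value`.
#' @export
gen_chr2_trace <- function(pulses, kin, fs_khz = 20, duration_ms = NULL,
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(pulses, "pulse_train"), inherits(kin, "chr2_kinetics"),
            fs_khz >= 10)
  if (is.null(duration_ms))
    duration_ms <- max(pulses$onsets) + 10 * kin$tau_decay
  dt <- 1 / fs_khz
  t <- seq(0, duration_ms, by = dt)
  v <- numeric(length(t))
  span <- min(45 * kin$tau_decay, duration_ms)
  n_span <- ceiling(span / dt)
  kern <- chr2_kernel(seq(0, n_span) * dt, kin)
  for (on in pulses$onsets) {
    i0 <- floor(on / dt) + 1L
    if (i0 > length(t)) next
    idx <- i0:min(i0 + n_span, length(t))
    v[idx] <- v[idx] + chr2_kernel(t[idx] - on, kin)[seq_along(idx)]
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  data.frame(time_ms = t, value = v)
}

#' Simulate a pacemaker spike train perturbed through its PRC
#'
#' Phase-model pacemaker: the intrinsic phase advances at the natural rate
#' (optionally with Gaussian jitter of the unperturbed period, drawn
#' independently per cycle) and a spike is emitted whenever the phase
#' crosses 1 (resetting to 0). Perturbations act through the PRC `Z`:
#'
#' * barrage stimulus (a [pulse_train()]): each pulse advances the phase
#'   instantaneously by `a_eff * Z(phi)` (weak-perturbation regime);
#' * sinusoidal drive (`drive = list(f, A)`): the phase obeys
#'   `dphi/dt = f0 - A * cos(2*pi*f*t) * Z(phi)`, integrated with
#'   fixed-step 4th-order Runge-Kutta; spike times are located by linear
#'   interpolation of the crossing step.
#'
#' @param duration_ms length of the simulated train in ms.
#' @param f0 natural firing rate in spikes/s.
#' @param prc a [triangular_prc()] with zero offset (or any function of
#'   phase).
#' @param stimulus optional [pulse_train()] for barrage mode.
#' @param drive optional list `list(f = Hz, A = amplitude)` for sinusoidal
#'   mode (mutually exclusive with `stimulus`). The drive starts at
#'   stimulus phase 0 at `t = 0`.
#' @param a_eff per-pulse phase advance at the PRC peak (barrage mode).
#'   The default 0.02 with the 6 ms barrage raises the firing rate by
#'   roughly a quarter, in the range of weak-perturbation experiments.
#' @param jitter_sd SD of the per-cycle period jitter, as a fraction of the
#'   natural period (0 disables jitter).
#' @param phi0 initial intrinsic phase (default drawn uniformly).
#' @param dt_ms integration step for the sinusoidal mode (ms).
#' @param seed optional integer seed.
#' @return A [spike_train()] with window `c(0, duration_ms)`.
#' @export
gen_pacemaker <- function(duration_ms, f0 = 7, prc = triangular_prc(0.8),
                          stimulus = NULL, drive = NULL, a_eff = 0.02,
                          jitter_sd = 0.02, phi0 = NULL,
                          dt_ms = (1000 / f0) / 500, seed = NULL) {
  stopifnot(duration_ms > 0, f0 > 0)
  if (!is.null(stimulus) && !is.null(drive))
    stop("supply either a pulse-train stimulus or a sinusoidal drive, not both")
  if (!is.null(seed)) set.seed(seed)
  zfun <- if (is.function(prc)) prc else function(p) predict(prc, p)
  if (!is.null(prc) && inherits(prc, "triangular_prc") &&
      abs(zfun(1)) > 0.1 * abs(prc$amp))
    warning("PRC has a sizeable offset at the spike threshold; results assume a zero-offset PRC")
  t0_ms <- 1000 / f0
  if (is.null(phi0)) phi0 <- stats::runif(1)
  draw_period <- function() {
    if (jitter_sd == 0) return(t0_ms)
    t0_ms * max(1 + stats::rnorm(1, 0, jitter_sd), 0.2)
  }
  spikes <- numeric(ceiling(duration_ms / t0_ms * 2) + 16L)
  ns <- 0L
  push <- function(ts) {
    ns <<- ns + 1L
    if (ns > length(spikes)) spikes <<- c(spikes, numeric(length(spikes)))
    spikes[ns] <<- ts
  }
  if (is.null(drive)) {
    # event-driven: linear phase advance between pulses
    onsets <- if (is.null(stimulus)) numeric(0) else
      stimulus$onsets[stimulus$onsets >= 0 & stimulus$onsets < duration_ms]
    if (!is.null(stimulus) && a_eff * max(abs(zfun(seq(0, 1, by = 0.01)))) > 0.1)
      warning("per-pulse phase advance exceeds 0.1: outside the weak-perturbation regime")
    events <- c(onsets, duration_ms)   # sentinel closes the window
    t <- 0; phi <- phi0; period <- draw_period()
    for (k in seq_along(events)) {
      ev <- events[k]
      repeat {
        t_cross <- t + (1 - phi) * period
        if (t_cross <= ev) {
          t <- t_cross
          push(t)
          phi <- 0
          period <- draw_period()
        } else {
          phi <- phi + (ev - t) / period
          t <- ev
          break
        }
      }
      if (k < length(events)) {          # apply the pulse kick
        phi <- phi + a_eff * zfun(phi)
        if (phi >= 1) { push(t); phi <- 0; period <- draw_period() }
      }
    }
  } else {
    stopifnot(is.list(drive), !is.null(drive$f), !is.null(drive$A))
    f_hz <- drive$f; A <- drive$A
    dt <- dt_ms
    rate <- 1 / draw_period()            # phase per ms, jittered per cycle
    dphi <- function(t, phi, rate)
      rate - (A / 1000) * cos(2 * pi * f_hz * t / 1000) * zfun(phi)
    t <- 0; phi <- phi0
    n_steps <- ceiling(duration_ms / dt)
    for (i in seq_len(n_steps)) {
      k1 <- dphi(t, phi, rate)
      k2 <- dphi(t + dt / 2, phi + dt / 2 * k1, rate)
      k3 <- dphi(t + dt / 2, phi + dt / 2 * k2, rate)
      k4 <- dphi(t + dt, phi + dt * k3, rate)
      step <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (step <= 0)
        stop("drive is strong enough to stall the pacemaker; reduce A")
      if (phi + step >= 1) {
        tc <- t + dt * (1 - phi) / step
        if (tc <= duration_ms) push(tc)
        phi <- phi + step - 1
        if (phi >= 1) stop("multiple phase crossings in one step; reduce dt_ms")
        rate <- 1 / draw_period()
      } else {
        phi <- phi + step
      }
      t <- t + dt
    }
  }
  if (ns == 0L) stop("no spikes emitted; check duration and rates")
  spike_train(sort(spikes[seq_len(ns)]), window = c(0, duration_ms))
}

#' Synthesize stimulus/response trace pairs for the cable model
#'
#' Forward model of the electrotonic-properties experiment: for each
#' driving frequency the stimulus is `cos(2*pi*f*t)` and the somatic
#' response is the band-model sinusoid delayed by the dendritic phase plus
#' the somatic correction `Phi_S`, low-pass attenuated by the somatic
#' membrane, with optional additive white noise. The ground-truth
#' parameters are attached so recovery can be tested.
#'
#' @param freqs driving frequencies in Hz (protocol range 0.25-16 Hz).
#' @param cable a [cable_params()]; the band `[r_inner, r_outer]` defines
#'   the illuminated region (use `r_inner = 0` for the soma-anchored band
#'   the fitting model assumes).
#' @param noise_sd additive Gaussian noise SD, relative to the response
#'   amplitude at each frequency.
#' @param duration_ms trace length per frequency (ms).
#' @param fs_khz sampling rate in kHz.
#' @param seed optional integer seed.
#' @return A list of sessions, one per frequency, each a list with
#'   `freq_hz`, `stim` and `resp` (trace data frames); ground truth in
#'   `attr(, "truth")` (`tau`, `rho`).
#' @export
gen_cable_sweep <- function(freqs, cable = cable_params(tau = 10, lambda = 1,
                                                        r_outer = 0.44),
                            noise_sd = 0, duration_ms = 3000, fs_khz = 2,
                            seed = NULL) {
  stopifnot(all(freqs > 0), inherits(cable, "cable_params"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs_khz
  t <- seq(0, duration_ms - dt, by = dt)
  out <- lapply(freqs, function(f) {
    omega <- omega_rad_ms(f)
    fr <- cable_F_phasor(cable$r_inner, omega, cable)
    fR <- cable_F_phasor(cable$r_outer, omega, cable)
    z <- cable$kappa * (fr$amp * exp(-1i * fr$phase) -
                        fR$amp * exp(-1i * fR$phase))
    phi_dend <- (-Arg(z)) %% (2 * pi)
    phi_s <- soma_phase(f, cable$tau)
    amp <- Mod(z) / sqrt(1 + (omega * cable$tau)^2)
    resp <- amp * cos(omega * t - phi_dend - phi_s)
    if (noise_sd > 0) resp <- resp + stats::rnorm(length(t), 0, noise_sd * amp)
    list(freq_hz = f,
         stim = data.frame(time_ms = t, value = cos(omega * t)),
         resp = data.frame(time_ms = t, value = resp))
  })
  attr(out, "truth") <- list(tau = cable$tau,
                             rho = cable$r_outer / cable$lambda)
  out
}

#' Extract phase-versus-frequency data from a cable sweep
#'
#' Applies [ccf_peak()] to every session of a [gen_cable_sweep()] result
#' (or any list of sessions with `freq_hz`, `stim`, `resp`) and returns the
#' measured phase delays as a [phase_freq_data()] table ready for
#' [fit_electrotonic()].
#'
#' @param sweep a list of sessions as produced by [gen_cable_sweep()].
#' @param condition condition label stored in the output.
#' @return A [phase_freq_data()] object.
#' @export
sweep_phases <- function(sweep, condition = NA_character_) {
  stopifnot(is.list(sweep), length(sweep) >= 1L)
  f <- vapply(sweep, `[[`, numeric(1), "freq_hz")
  phi <- vapply(sweep, function(s)
    ccf_peak(s$resp, s$freq_hz, stim = s$stim)$phi_rad, numeric(1))
  o <- order(f)
  phase_freq_data(f[o], phi[o], unit = "rad", condition = condition)
}
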