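# dendrophase

Tools for asking how a pacemaker neuron's dendrites shape its response to
input — built for the kind of experiment in which autonomously firing
basal-ganglia output neurons (substantia nigra pars reticulata GABAergic
cells, firing regularly at ~7 spikes/s) are perturbed optogenetically
either at the soma and proximal dendrites or across the entire dendritic
arbor, and the question is how the *location* of the input changes the
*timing* of its somatic effect.

The package implements four connected pieces of theory and the estimation
machinery around them:

1. **Quasi-linear cable model.** A semi-infinite cable attached to a
   voltage-clamped soma filters a sinusoidal dendritic drive into a
   phase-shifted somatic current. With surds
   `p, q = sqrt((sqrt(α²+β²) ± α)/2)` (passive cable: `α = 1`,
   `β = ωτ`), point stimulation at distance R gives the unbounded shift
   `Φ_R = (R/λ) q`, a band anchored at the soma the bounded shift
   `Φ_0 = arctan(q/p) − arctan( sin(Rq/λ) / (e^{Rp/λ} − cos(Rq/λ)) )`,
   and the soma adds `Φ_S = arctan(ωτ)`. Fitting `(Φ_0 + Φ_S)/2π` to
   phase-versus-frequency data estimates the membrane time constant τ and
   the electrotonic extent ρ = R/λ of the stimulated region
   (`fit_electrotonic()`), with phases extracted from traces by
   cross-correlation peaks (`ccf_peak()`).

2. **PRC estimation.** The phase response curve Z(φ) is estimated from
   Poisson-like pulse barrages by dividing every interspike interval into
   50 phase bins and regressing ISI durations on mean-subtracted per-bin
   pulse counts (`bin_pulses()`, `estimate_prc()`); an acute triangle
   (peak phase θ, amplitude A, offset C) is fit to the tabulated curve
   (`fit_triangle()`), and its Fourier series `Ẑ_0 = 1/2`,
   `Ẑ_k = (e^{−2πikθ} − 1)/(4π²θ(1−θ)k²)` is exposed
   (`triangle_fourier()`). ChR2 photocurrent kinetics are fit as
   `A(e^{−t/τ_rise} − e^{−t/τ_decay})` (`fit_chr2_kernel()`).

3. **Population rate model.** The Fokker–Planck rate response of a
   pacemaker population to a step input,
   `R(t) = F_base + H(t)·(F_steady−F_base)/Ẑ_0 · Σ_k Ẑ_k e^{−(σ²k²/2 + 2πik/T_0)t}`,
   is evaluated and fit to peri-stimulus time histograms
   (`compute_psth()`, `psth_model()`, `fit_psth()`); the initial PSTH rise
   mirrors the falling flank of the PRC, so a later PRC peak means an
   earlier population peak.

4. **Entrainment.** Under periodic drive, each spike's effective phase ψ
   and the following perturbed period T_p define the return map
   `ψ_{n+1} = ψ_n + T_p(ψ_n)/T mod 1`; stable fixed points are locking
   phases (`perturbed_periods()`, `fit_tp_curve()`, `build_map()`,
   `find_fixed_points()`, cobweb plots). For locked regimes T_p(ψ) is
   simulated from the phase equation
   `dφ/dt = f_0 − A cos(2π[ft+ψ]) Z(φ)` (`simulate_tp()`,
   `predict_locking()`). Circular statistics with bootstrap nulls
   quantify locking strength and phase (`circular_stat()`,
   `bootstrap_threshold()`, `bootstrap_phase_pvalue()`).

A seeded synthetic-data generator (`gen_barrage()`, `gen_chr2_trace()`,
`gen_pacemaker()`, `gen_cable_sweep()`) emulates every input the analyses
consume, so the full pipeline is testable with no external recordings.
Delimited-text readers/writers (`read_spike_file()`, `read_trace()`,
`write_results()`, ...) cover the interchange formats.

## Worked example

Simulate a full-field-like experiment and recover its parameters:

```r
library(dendrophase)

## electrotonic properties from a frequency sweep (tau = 11 ms, rho = 0.44)
sweep <- gen_cable_sweep(c(6, 8, 10, 12, 14, 16),
                         cable_params(tau = 11, lambda = 1, r_outer = 0.44),
                         noise_sd = 0.1, seed = 42)
fit_electrotonic(sweep_phases(sweep), stim_radius_known = 580)
#> Electrotonic fit (band model + somatic phase)
#>   tau = 10.94 ms,  rho = R/lambda = 0.4623
#>   lambda = 1255 (stimulation-radius units)
#>   fit over 6 frequencies, RMS residual 2.85e-04 cycles

## PRC from a 300 s pulse barrage through a triangular PRC (theta = 0.763)
pulses <- gen_barrage(duration_ms = 3e5, mean_ipi_ms = 6, seed = 1)
spikes <- gen_pacemaker(3e5, f0 = 7, prc = triangular_prc(0.763),
                        stimulus = pulses, a_eff = 0.02,
                        jitter_sd = 0.02, seed = 2)
fit_triangle(estimate_prc(bin_pulses(spikes, pulses)),
             force_zero_ends = TRUE)
#> Triangular PRC: theta = 0.7781, A = 0.02005, C = 0

## predicted locking phase of a proximally driven pacemaker
predict_locking(theta = 0.9, A = 5, f = 7, f0 = 7)
#>         psi     slope stable
#> 2 0.5362707 0.5518041   TRUE

## significance threshold for locking strength (100 ISIs per session)
bootstrap_threshold(n = 100, reps = 10000, seed = 1)
#> [1] 0.1732072
```

The electrotonic fit recovers the generating time constant (10.9 vs 11 ms)
and band extent (0.46 vs 0.44), placing the characteristic length near
1.3 mm for a 580-unit stimulation radius; the PRC regression recovers the
generating peak phase (0.778 vs 0.763) and per-pulse amplitude (0.0200 vs
0.02). A triangular PRC peaking at 0.9 driven at its natural 7 Hz with
amplitude 5 locks stably at effective phase 0.536 — just after the
depolarizing peak of the drive (phase 0.5) — and a circular-variance
amplitude above ~0.173 marks significant locking for 100-spike sessions.

## Vignette

`vignettes/dendrophase-methods.Rmd` documents the models, unit
conventions, numerical choices, the synthetic generator's scope, and known
limitations.
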