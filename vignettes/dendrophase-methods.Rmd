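---
title: "Dendritic filtering, phase response curves and entrainment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic filtering, phase response curves and entrainment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrophase)
```

This vignette documents the models implemented in **dendrophase**, the
assumptions behind them, the numerical choices made where the underlying
methods leave freedom, and what the bundled synthetic-data generator does
and does not emulate. The scientific setting is the autonomously pacemaking
GABAergic projection neuron (the substantia nigra pars reticulata is the
prototype): a cell firing regularly at ~7 spikes/s whose dendritic arbor
receives inputs at different distances from the soma, so that the *where*
of an input changes the *when* of its somatic effect.

## 1. The quasi-linear cable model

The dendrite is collapsed to a semi-infinite cable attached to a
voltage-clamped somatic compartment. Active conductances are linearized
about rest, so a sinusoidal drive at angular frequency $\omega$ propagates
through a medium characterized by two spectral functions
$\alpha(\omega), \beta(\omega)$; the passive cable has $\alpha = 1$,
$\beta = \omega\tau$ with $\tau$ the membrane time constant. All closed
forms are expressed through the surds

$$p = \sqrt{\tfrac{\sqrt{\alpha^2+\beta^2}+\alpha}{2}}, \qquad
  q = \sqrt{\tfrac{\sqrt{\alpha^2+\beta^2}-\alpha}{2}},$$

which satisfy $p^2 - q^2 = \alpha$ and $2pq = \beta$ exactly; $p$ controls
exponential attenuation per characteristic length $\lambda$ and $q$ the
distance-proportional phase delay. Illuminating a band $[r, R]$ of the
cable with temporal waveform $\cos\omega t$ injects a somatic current
$I(t) = \kappa\,[F(r,t;\omega) - F(R,t;\omega)]$, a pure sinusoid whose
phase delay is obtained from the peak of the cross-correlation with the
stimulus. Two limits have closed forms (`phase_shift_point()` and
`phase_shift_band()`): a narrow band at distance $R$ behaves like a point
source with unbounded shift $\Phi_R = (R/\lambda)\,q$, while a band
anchored at the soma has a shift $\Phi_0$ bounded by $\arctan(q/p)$. The
general band is handled by `solve_ccf_delay()`, which brackets the
stationary points of the CCF derivative on a 720-point grid over one
stimulus period, bisects to $10^{-10}$, and keeps the root with negative
curvature. A passive isopotential soma adds $\Phi_S = \arctan(\omega\tau)$
(`soma_phase()`), because the electrode records at the pipette tip, not at
the dendritic injection site.

**Units.** Time is in ms throughout the package, frequency inputs in Hz,
angular frequency $\omega = 2\pi f/1000$ rad/ms. Phases are radians in the
cable functions and cycles (= rad/$2\pi$) in fitted phase tables; the
field mixes both, so every interface documents which it uses.

**Phase extraction.** `ccf_peak()` computes the CCF of a sampled response
against the reference cosine as a time average over an integer number of
periods, scans lags at the sample resolution, and refines the peak with a
3-point parabolic interpolation. No sub-sample method is canonical here;
parabolic refinement of a sinusoidal peak is accurate to far below the
phase noise of any realistic trace and is validated in the tests against
an independent continuous maximization.

**Electrotonic fitting.** `fit_electrotonic()` fits $(\tau, \rho)$, with
$\rho = R/\lambda$ the electrotonic extent of the stimulated region, by
bounded nonlinear least squares of $(\Phi_0 + \Phi_S)/2\pi$ to measured
phase-versus-frequency data, by default over 6–16 Hz (low-frequency phases
are empirically the most variable, so they are excluded by default but the
window is configurable). Bounds are $\tau \in (0, 100]$ ms,
$\rho \in (0, 5]$. A small grid of starting values is tried and the best
fit kept: the residual surface is weakly curved in $\rho$ (the band term
$\Phi_0$ spans only ~0.01 cycles at proximal $\rho$), and a single start
occasionally lands in a shallow local minimum. For the same reason $\rho$
is only identifiable when phase errors are well below 0.01 cycles per
point; phases extracted by `ccf_peak()` from seconds-long traces at
signal-to-noise 10 have errors of a few $10^{-4}$ cycles, and the
parameter-recovery tests (which average the phase curves of six synthetic
cells, as the empirical analysis does) recover $\tau$ and $\rho$ with
under 10% RMS error at that noise level. The gain $\kappa$ is never
interpreted physically — only phases carry information here — and the
somatic holding potential is absorbed by baseline subtraction.

## 2. PRC estimation from pulse barrages

The phase response curve $Z(\varphi)$ — the phase advance per unit
perturbation as a function of the intrinsic phase $\varphi \in [0,1)$ at
which it arrives — is estimated from barrage experiments: Poisson-like
trains of brief light pulses with exponential inter-pulse intervals.
`bin_pulses()` divides each interspike interval into 50 equal phase bins
(bin $j$ centered at $(j-\tfrac12)/50$; bin duration scales with the ISI)
and counts pulses per bin. A pulse falling exactly on a spike is assigned
to the *following* interval (half-open ISIs); pulse timestamps are onsets,
matching the onset-to-onset interval convention. `estimate_prc()` then
regresses ISI durations on the grand-mean-subtracted counts
$\Delta p_{\alpha j}$ (ordinary least squares with intercept) and converts
the coefficients $b_j$ (ms per pulse) to phase units as
$Z(\varphi_j) = -b_j/\bar{T}$, with $\bar T$ the fitted intercept — the
mean ISI at zero pulse excess. The sign convention makes a
period-shortening pulse a positive phase advance. The normalization by the
fitted intercept (rather than the unperturbed period, which is not
observable during a barrage) is validated by parameter recovery on
synthetic data; the two differ by the relative rate change (~2% per 10% of
rate increase). Raw estimates may dip below zero near phases 0 and 1 when
the unperturbed period jitters; no clipping is applied, because the
triangle fit absorbs this as an offset.

`fit_triangle()` fits the acute triangle (peak phase $\theta$, amplitude
$A$, offset $C$) by profiling $\theta$: the amplitude and offset are
linear given $\theta$, so the residual is minimized on a $\theta$ grid and
polished with golden-section refinement, avoiding derivative trouble at
the kink. With `force_zero_ends = TRUE` the curve is pinned to $(0,0)$ and
$(1,0)$, which phase theory requires at the spike threshold. The Fourier
coefficients of the zero-offset unit triangle are closed-form
(`triangle_fourier()`), under the convention
$\hat Z_k = \int_0^1 Z(\varphi) e^{-2\pi i k\varphi}\,d\varphi$, fixed by
$\hat Z_0 = 1/2$.

ChR2 photocurrent kinetics are summarized by the double exponential
$A(e^{-t/\tau_\mathrm{rise}} - e^{-t/\tau_\mathrm{decay}})$
(`fit_chr2_kernel()`). As printed, the bracket is negative for
$\tau_\mathrm{rise} < \tau_\mathrm{decay}$, so an inward (plotted-positive)
current has $A < 0$; the fit leaves the sign of $A$ free and relabels time
constants so that $\tau_\mathrm{rise}$ always names the faster edge.

## 3. The population rate (PSTH) model

For a population of pacemakers receiving a step increase in drive at
$t = 0$, the Fokker–Planck treatment of the phase density yields a
closed-form firing rate built from the PRC's Fourier series:

$$R(t) = F_\mathrm{base} + H(t)\,
  \frac{F_\mathrm{steady}-F_\mathrm{base}}{\hat Z_0}
  \sum_{k=-K}^{K} \hat Z_k\,
  e^{-\left(\sigma^2 k^2/2 + 2\pi i k/T_0\right) t}.$$

`psth_model()` evaluates this with $K = 100$ by default (doubling $K$
changes values by less than $10^{-3}$ relative, which the tests check);
conjugate symmetry cancels the imaginary part, and the implementation
asserts the cancellation numerically. The initial rise of $R(t)$ mirrors
the falling flank of the PRC, so a later PRC peak yields an earlier PSTH
peak — the ordering the package treats as the model's defining qualitative
prediction.

**The unit of $\sigma$.** The phase-diffusion parameter multiplies
$k^2 t/2$ in the exponent, and the package takes $t$ in *seconds* there
(so $\sigma$ is in s$^{-1/2}$), while the rotation term uses the baseline
period in ms. The empirically reported values of $\sigma$ (about 4–6)
imply a $k=1$ relaxation time $2/\sigma^2$ of 60–105 ms under this
convention, matching the tens-of-milliseconds transients such fits
describe; with $t$ in ms those same numbers would extinguish the transient
within a tenth of a millisecond, leaving nothing to fit. The seconds
convention is therefore the only self-consistent reading, and it is the
one implemented.

`fit_psth()` fixes $F_\mathrm{base}$ and $F_\mathrm{steady}$ at the
measured baseline and steady-state rates (by default the windows
$[-3, 0)$ s and $[4, 9)$ s around onset, following the 3 s baseline + 9 s
barrage protocol) and estimates only $(\sigma, \theta)$ by least squares
over the first 50 ms after onset (configurable). The optimizer is
L-BFGS-B from a grid of starts spanning $\sigma \in [0.1, 8]$: weakly
damped (nearly deterministic) populations and strongly damped ones live in
different basins, and a single start is unreliable.

## 4. Entrainment and the effective-phase return map

Under a periodic drive of period $T$ near the natural period, each spike
is labeled by its *effective phase* $\psi \in [0,1)$ in the stimulus cycle
(`effective_phases()`), and the following perturbed period $T_p$ is paired
with it (`perturbed_periods()`). Unlocked sessions visit all phases and
support a 3-mode Fourier fit of $T_p(\psi)$ (`fit_tp_curve()`; a circular
coverage gap above 0.25 cycles aborts with a "locked session" error, since
a locked cell never explores the curve). The return map

$$\psi_{n+1} = \psi_n + T_p(\psi_n)/T \bmod 1$$

is built by `build_map()`; `find_fixed_points()` locates all fixed points
of the lifted map by bracketing on 1024 samples and bisecting to
$10^{-10}$, computes slopes by central difference ($h = 10^{-5}$), and
calls a fixed point stable when $|\text{slope}| < 1$ — a stable fixed
point is the locking phase.

For locked regimes, where the curve cannot be measured, `simulate_tp()`
derives $T_p(\psi)$ from the phase model
$d\varphi/dt = f_0 - A\cos(2\pi[ft+\psi])\,Z(\varphi)$, integrated from
$\varphi = 0$ until $\varphi = 1$ with classical fixed-step 4th-order
Runge–Kutta at $dt = T_0/10^4$ and linear interpolation of the final
crossing. Under this sign convention the depolarizing peak of the drive
sits at effective phase 0.5, and spikes lock at or shortly after the
stimulus peak; the drive amplitude $A$ is the dimensionless product
multiplying the *unit* triangle (the empirical per-pulse amplitude is not
propagated here). `simulate_map()` evaluates $T_p$ on 256 equally spaced
phases and interpolates with a periodic cubic spline. With
$f = f_0 = 7$ Hz and $A = 5$ the map for a triangle peaking at
$\theta = 0.9$ has its stable fixed point at $\psi^* \approx 0.536$ and
the $\theta = 0.75$ triangle at $\psi^* \approx 0.599$ — the later-peaked
PRC locks earlier, which is the package's second defining qualitative
prediction. An independent event-by-event simulation of the driven
oscillator (`gen_pacemaker()` with a sinusoidal drive), which never
constructs the map, reproduces these locking phases to better than 0.01
cycles.

Locking strength and phase are summarized by the circular variance vector
(`circular_stat()`), the mean of the unit phasors $e^{2\pi i\psi}$.
Significance is assessed against surrogate series of uniform phases:
`bootstrap_threshold()` returns the 95th percentile of surrogate
amplitudes (~0.173–0.175 for series of 100, consistent with the Rayleigh
approximation $\sqrt{-\ln 0.05/n}$, and scaling as $1/\sqrt n$).
`bootstrap_phase_pvalue()` tests whether a condition's mean locking phase
could arise from a reference condition's distribution of locking vectors,
resampling reference phases with weights proportional to vector amplitude;
"at least as extreme" is measured two-sided on the shorter circular arc,
since the method description leaves sidedness open. Both take explicit
seeds; default 10,000 replicates.

```{r}
predict_locking(theta = 0.9, A = 5, f = 7, f0 = 7)
bootstrap_threshold(n = 100, reps = 2000, seed = 1)
```

## 5. The synthetic-data generator

Every analysis input can be produced in code, with the statistical
structure the analyses assume, under fixed seeds:

* `gen_barrage()` — pulse trains with onset-to-onset intervals drawn as
  one pulse width plus an exponential, keeping the nominal mean interval
  (6 ms or 2.17 ms) exact while preventing overlap.
* `gen_chr2_trace()` — linear superposition of double-exponential kernels
  at 20 kHz.
* `gen_pacemaker()` — a phase-model pacemaker at 7 spikes/s: barrage
  pulses act as instantaneous kicks $a_\mathrm{eff} Z(\varphi)$
  (default $a_\mathrm{eff} = 0.02$, chosen so the 6-ms barrage raises the
  rate by roughly a quarter, inside the empirically observed 19–33%
  range); sinusoidal drives are integrated continuously. Per-cycle
  Gaussian period jitter (default SD 2% of the period) reproduces the
  small negative excursions of raw PRC estimates near phases 0 and 1.
* `gen_cable_sweep()` — stimulus/response trace pairs whose responses are
  band-model sinusoids with the somatic low-pass correction plus white
  noise, with ground truth attached.

What the generator does *not* emulate: conductance-based membrane
dynamics, dendritic nonlinearities, cell-to-cell heterogeneity of natural
rates, ChR2 desensitization, and recording artifacts. Passing
parameter-recovery tests on these data therefore demonstrates the
estimators' correctness and statistical power under the model's own
assumptions, not robustness to every feature of real recordings.

**Problem sizes in the tests.** The PRC recovery study uses 300 s
continuous barrages (20 seeds per peak-phase value); the population study
uses 19 cells × 25 sweeps of the 3 s + 9 s protocol under the dense
(2.17 ms) barrage condition, whose ~1/3 rate increase gives the PSTH
transient enough contrast for the 4-ms-bin fit — under the sparse 6-ms
condition the transient amplitude (~1.5 spikes/s) is comparable to the
shot noise of 475 sweeps and single-run peak-phase errors of ±0.1 are
expected, which is a statement about statistical power at that session
size, not about the estimator.

## 6. Degenerate inputs and edge policies

* Zero-width illumination bands warn and return a zero response; the CCF
  of a flat trace is an error, not a NaN.
* The band shift at $R = 0$ returns the analytic limit 0 (the 0/0 form is
  guarded).
* Empty PRC phase bins (never stimulated) are dropped from the regression
  and reported, keeping the design full rank.
* Flat PRC tables have no identifiable peak and raise an error.
* An identity-like return map (every point fixed) is flagged degenerate
  rather than enumerating fixed points.
* A drive strong enough to stall the pacemaker (phase derivative
  non-positive, or no crossing within 10 natural periods) raises an error
  instead of silently returning a long period.

## 7. Known limitations

* The cable model is a single unbranched semi-infinite cable with sharp
  illumination edges; branched morphologies, finite cables and soft
  illumination falloff are out of scope.
* $\rho$ is weakly identified from phase data with errors at or above
  0.01 cycles; the package reports residuals so users can judge.
* The PSTH model is the linear (weak-perturbation) rate response with a
  triangular PRC; other PRC families and the full phase-density evolution
  are not implemented.
* The amplitude-weighted bootstrap for comparing locking-phase
  distributions is one reading of a loosely specified procedure; it is
  seed-controlled and calibration-tested, but alternative weightings are
  defensible.
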