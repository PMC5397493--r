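---
title: "Orientation detection across cortical functional states: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation detection across cortical functional states: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringstate)
```

## The scientific question

Cortical activity looks different in different functional states: awake,
engaged animals show desynchronized activity, quiet or sleeping animals show
synchronized activity, and neuromodulators such as acetylcholine switch
between these regimes by simultaneously lowering the neurotransmitter
release probability of cortical synapses and depolarizing cortical neurons.
`ringstate` asks a quantitative version of the question "which state is best
for seeing?": in a model of a primary-visual-cortex orientation hypercolumn,
how precisely can the orientation of a briefly flashed stimulus be read out
of the population activity, as a function of the functional state?

The package's answer, reproduced by its test suite, is that a downstream
readout that samples the population *sparsely* does best at an intermediate
release probability: too low and single-unit rates are so small that the
spiking readout is shot-noise limited; too high and the network's own bump
dynamics wander away from the stimulus orientation. An idealized readout
with access to all units only sees the second effect, so its error grows
monotonically with release probability.

## The model

The hypercolumn is a ring of \(N\) rate units, unit \(i\) having preferred
orientation \(\theta_i = i\pi/N\). Rates \(m_i\), synaptic resources
\(x_i\) and noise currents \(I^{noise}_i\) evolve as

\[
\tau \dot m_i = -m_i + g\!\Big(\tfrac{1}{N}\sum_j W_{ij}\, U x_j m_j
  + I^{inp}_i + I^{noise}_i + I_0\Big), \qquad
g(y) = \log(1 + e^{y}),
\]
\[
\dot x_i = \frac{1 - x_i}{\tau_{rec}} - U x_i m_i, \qquad
\tau_n \dot I^{noise}_i = -I^{noise}_i + \sigma\sqrt{2\tau_n}\,\xi_i(t),
\]

with cosine connectivity \(W_{ij} = J_0 + J_1 \cos(2(\theta_i - \theta_j))\)
(uniform inhibition \(J_0 < 0\), like-to-like excitation \(J_1 > 0\)).
Short-term depression is the classic resource model: each unit releases a
fraction \(U\) of its available resource per unit activity and recovers with
time constant \(\tau_{rec}\). The noise is an independent
Ornstein–Uhlenbeck process per unit with stationary standard deviation
\(\sigma\) and correlation time \(\tau_n\).

The recurrent sum carries an explicit \(1/N\): with it, the calibrated
baseline inputs \(I_0\) come out of order unity across the whole
release-probability range, which is the regime the model is meant to
operate in; without it they would scale with \(N\).

### Reference parameters

| symbol | meaning | default |
|---|---|---|
| `N` | ring units | 200 |
| `J0` | uniform coupling | −12 |
| `J1` | modulated coupling | 30 |
| `tau` | rate time constant | 0.01 s |
| `tau_rec` | resource recovery | 0.8 s |
| `tau_n` | noise correlation time | 0.1 s |
| `sigma` | noise stationary sd | 2 |
| `U` | release probability | state variable, (0, 1] |
| `I0` | baseline depolarization | calibrated per U |
| `dt` | integration step | 0.002 s |
| `C` | stimulus amplitude | 5, 10, 20, 40 |
| `T` | stimulus duration | 0.05 s (0.2 s also valid) |
| `Freq` | stimulus rate | 4 Hz |
| `tau_rd` | readout time constant | 0.02 s |

`model_params()` enforces the structural constraints (`dt < tau`,
`0 < U <= 1`, positive time constants).

## Numerical integration

The system is integrated by the Euler–Maruyama method with
`dt = 0.002` s. The compiled core evaluates the recurrent drive in
\(O(N)\) per step using
\(\cos(2(\theta_i - \theta_j)) = \cos 2\theta_i \cos 2\theta_j +
\sin 2\theta_i \sin 2\theta_j\), which is algebraically exact; the R-level
`network_step()` uses the full matrix product, and a test pins the two
routes against each other to \(10^{-10}\).

Choices worth knowing about:

* **Initial conditions and burn-in.** Runs start from full resources
  (\(x_i = 1\)), zero noise current and uniform rates \(g(I_0)\); the first
  10 s of every run are discarded before any statistic is computed.
* **No clamping.** If a rate becomes nonpositive or a resource leaves
  \((0, 1]\) the simulation stops with an error naming the time and unit.
  These invariants hold mathematically for `dt < tau`; violating them
  signals parameter misuse rather than something to repair silently.
* **RNG streams per concern.** Network noise uses R's RNG (seeded with
  `set.seed`); stimulus schedules use their own seed; spike sampling inside
  the compiled readout uses a separate counter-based stream. Consequently
  changing the readout configuration never perturbs the network trajectory,
  and every result row is regenerable bit-for-bit from its recorded seeds.
* **Uniform-state stability.** The noiseless uniform state is an exact
  solution at any \(U\), but above roughly \(U \approx 0.2\) it is linearly
  unstable, so in floating point a bump eventually grows out of round-off.
  The symmetry tests therefore probe the stable low-\(U\) regime.

## Calibrating functional states

A functional state is a pair \((U, I_0)\) constrained so that the
stimulus-free mean rate

\[
\langle m \rangle = \frac{1}{T_{sim} N} \int_0^{T_{sim}}\!\! \sum_i m_i(t)\, dt
\]

stays at 0.5 Hz, reflecting the observation that spontaneous cortical rates
barely change across states. `calibrate_I0()` solves for \(I_0\) by
bisection on \([-20, 20]\): each objective evaluation is a full 200 s
stochastic simulation run with *common random numbers* (the same noise seed
at every iterate), which makes the objective effectively deterministic and
monotone so bisection is robust; the inner stopping tolerance is half the
reported one (0.025 Hz by default) so that the final *independent-seed*
validation run has margin to land within the stated ±0.05 Hz. Bisection
was preferred over secant/Brent because the objective still carries a small
seed-dependent bias and bracket maintenance is what makes the search immune
to it.

The resulting \(I_0(U)\) curve is non-monotonic: at low \(U\) the dominant
effect of increasing \(U\) is stronger uniform inhibition (\(|J_0|\)
filtered through the spatially flat activity), so \(I_0\) must rise; once
noise-driven spatial fluctuations become comparable to the mean activity,
the like-to-like excitation \(J_1\) dominates and \(I_0\) must fall again.
The peak sits near \(U = 0.2\) at the reference parameters.

## Stimuli

Oriented stimuli are brief cosine-profiled current injections
\(I^{inp}_i = C\,\mathrm{rect}((t - t_k)/T)\cos(2(\theta^{inp}_k - \theta_i))\).
Onset times are a Poisson stream of rate `Freq` thinned sequentially with a
refractory period `T`, so windows never overlap; the realized rate is
therefore slightly below `Freq` (about \(Freq/(1 + Freq\,T)\); the thinning
rule is pinned against an independent event-by-event oracle in the tests).
Orientations are uniform on \([0, \pi)\). The rectangular window is
implemented half-open, \([t_k, t_k + T)\), so windows tile exactly on the
time grid. The generator emulates the *statistics* of brief flashed
stimuli only: no drifting gratings, contrast ramps or overlapping stimuli,
so passing tests say nothing about temporally extended stimulation.

## Readout and decoding

Two population vectors are computed. The exact readout is the second
spatial Fourier coefficient of the rate profile,
\(ER(t) = \frac{1}{N}\sum_j e^{-2i\theta_j} m_j(t)\) — the noise-free
decoding limit. The sparse readout models a downstream area that sees only
\(N_{read}\) randomly chosen units (chosen once per condition, uniformly
without replacement) through their spikes: each step, unit \(j\) emits a
Poisson count with mean \(m_j\,dt\), and the counts drive a leaky
integrator

\[
\tau_{rd} \dot R = -R + \frac{1}{N_{read}} \sum_j e^{-2i\theta_j}
\frac{\chi_j(t)}{dt}.
\]

Spikes enter as unit-area impulses (counts divided by \(dt\)), which makes
the integrator's fixed point independent of the step size and makes
\(E[R]\) exactly the population vector of the sampled rates; the tests
verify this unbiasedness and the \(1/N_{read}\) shot-noise variance scaling
against closed-form oracles. \(\tau_{rd}\) is not part of the reference
parameter table; the default 0.02 s is a plausible readout membrane/synaptic
integration time, it is configurable, and it is recorded with every result.

The decoded orientation is \(\hat\theta = (-\arg R / 2) \bmod \pi\).
Orientation is a circular variable of period \(\pi\), so detection errors
use the wrapped distance \(\min(|\Delta|, \pi - |\Delta|) \in [0, \pi/2]\):
a decoder that ignores the stimulus scores 45° on average, which is the
chance floor all reported errors should be read against. Samples where
\(|R| = 0\) exactly (possible in the first readout steps before any spike)
have no defined angle; they are excluded from averages and counted, rather
than assigned a default error.

The detection error of a condition averages the wrapped error over every
in-stimulus-window sample, then minimizes over a readout lag scanned on a
grid (default 0–0.2 s in 2 ms steps, ties to the smallest lag) because the
leaky integrator needs time to react; all lags are scored on the same
stimulus windows so the curve is comparable across the grid. Optimal lags
shrink as \(U\) (and hence evoked rates) grow.

## Bump diagnostics

Spontaneous bump strength is summarized by the modulation index
\(M(t) = |ER(t)| / \bar m(t)\): 0 for uniform activity, 0.5 for a full
cosine profile, 1 for a single active unit. The bump onset over a
\(U\) grid is defined as the first crossing of the half-rise threshold,
midway between the curve's minimum (low-\(U\) plateau) and maximum
(high-\(U\) saturation). Two caveats are inherent to this index: finite
\(N\) gives it a noise floor even for asynchronous activity (about 0.1 at
the reference parameters), and it grows smoothly with \(U\), so its
half-rise crossing is an operational definition of "bumps appear" that can
sit below what visual inspection of activity rasters would suggest — at the
reference parameters the half-rise lands around \(U = 0.25\), whereas
rasters show prominent discrete bump events from roughly \(U \approx 0.4\).

## Problem sizes and reproducibility

The package defaults to desk-scale runs: calibration, bump scans and sweep
conditions all simulate 200 s (plus 10 s burn-in) rather than the 2000 s a
production study would use, and report the number of stimuli per condition
(about 660 at `Freq = 4`, `T = 0.05`) so the statistical power of any
number is explicit. All sweep trends quoted in the README and asserted in
the tests are computed at these durations with fixed seeds; they are
trends, not precise error values — rerunning at 2000 s tightens every
Monte-Carlo estimate but changes no qualitative conclusion we have
observed.

## Known limitations

* Rate units stand in for whole columns; there are no spiking neurons, no
  conductances and a single effective inhibitory channel.
* The readout decodes only during stimulus windows (plus lag); it does not
  address detection *timing* or discrimination between near-simultaneous
  stimuli, and the lag is a free parameter optimized per condition.
* The calibration target (0.5 Hz) and its tolerance (±0.05 Hz) are
  modeling choices; the underlying observation is only that mean rates are
  approximately state-invariant.
* The bump-modulation index is a convenient scalar, not a detector of
  discrete bump events; see the caveats above.
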