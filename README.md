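# ringstate

Simulation and decoding pipeline for studying how the **functional state of
visual cortex** affects the precision of orientation detection, in a
firing-rate ring model of a V1 hypercolumn with short-term synaptic
depression.

Cortical states (quiet wakefulness, engagement, sleep) are switched by
neuromodulators that lower the neurotransmitter release probability `U` of
cortical synapses while depolarizing neurons. `ringstate` emulates a state
as a pair `(U, I0)` constrained to a fixed stimulus-free mean firing rate,
drives the network with brief oriented stimuli, and measures how well the
stimulus orientation can be decoded from population activity — by an exact
readout with access to all units, and by a biologically constrained sparse
readout that sees Poisson spikes from only `N_read` units. The headline
phenomenon: the sparse readout is most precise at an **intermediate**
release probability, and the optimum shifts to lower `U` as the readout
gets denser or the stimuli stronger.

## Model

A ring of `N` rate units, unit `i` preferring orientation
θᵢ = iπ/N, with

```
τ dmᵢ/dt = −mᵢ + g( (1/N) Σⱼ Wᵢⱼ U xⱼ mⱼ + Iᵢ_inp + Iᵢ_noise + I0 ),   g(y) = log(1+eʸ)
dxᵢ/dt   = (1 − xᵢ)/τ_rec − U xᵢ mᵢ
τₙ dIᵢ_noise/dt = −Iᵢ_noise + σ √(2τₙ) ξᵢ(t)
Wᵢⱼ = J0 + J1 cos(2(θᵢ − θⱼ))
```

integrated by Euler–Maruyama (`dt = 0.002 s`, compiled core). Decoding uses
the complex population vector: exact `ER(t) = (1/N) Σⱼ exp(−2iθⱼ) mⱼ(t)`
and a leaky-integrated sparse version driven by Poisson spike counts; the
decoded orientation is `−arg(R)/2 mod π`, scored by the wrapped orientation
distance (≤ 90°; a stimulus-blind decoder scores 45°), minimized over a
readout lag.

## Worked example

Calibrate one functional state (here with a 60 s calibration run for
brevity), then measure detection precision at stimulus amplitude `C = 20`
for sparse readouts of 20 and 80 units:

```r
library(ringstate)
p <- model_params()                      # reference network constants
cal <- calibrate_I0(0.25, p, sim_duration = 60, seed = 7)
cal
#> Calibration: U = 0.25 -> I0 = -0.46875 (validated mean rate 0.4994 Hz, target 0.5 +/- 0.05)

cfg <- sweep_config(U_grid = 0.25, N_read_grid = c(20L, 80L), C_grid = 20,
                    T_sim = 60, master_seed = 7)
rows <- run_condition(0.25, cal$I0, c(20L, 80L), 20, cfg, p)
rows[, c("readout", "N_read", "min_err_deg", "optimal_lag_s", "bump_index", "n_stimuli")]
#>  readout N_read min_err_deg optimal_lag_s bump_index n_stimuli
#>   sparse     20    6.926545         0.042  0.4810788       192
#>   sparse     80    4.300223         0.038  0.4810788       192
#>    exact    200    1.808837         0.016  0.4810788       192
```

Reading the numbers: at this state the 20-unit readout decodes the stimulus
orientation to about 6.9° (of a 45° chance floor) at its best lag of 42 ms;
sampling 80 units cuts the error to 4.3°, and the noise-free exact readout
marks the 1.8° floor set by the network's own bump dynamics. `bump_index`
is the time-averaged spatial modulation `|ER|/mean rate` of the run, and
192 stimuli contributed to the average. Sweeping `U` with
`calibrate_grid()` + `run_sweep()` traces the full error-vs-state curves
and `find_optimal_U()` locates each readout's best state.

A thin CLI over the same functions is installed at
`system.file("cli", "ringstate", package = "ringstate")` with subcommands
`calibrate`, `bumps`, `sweep` and `report`.

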