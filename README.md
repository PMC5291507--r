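# lsanet

Simulation toolkit for **learning by stimulation avoidance (LSA)** in spiking
neural networks: the observation that a random recurrent network equipped with
nothing but spike-timing-dependent plasticity (STDP) can be *trained* by an
environment that stimulates it until a desired firing pattern appears and then
stops. Patterns that terminate stimulation are strengthened; patterns that
trigger it are pruned. No reward signal, no value function — the contingency
between network activity and external input does all the work.

The package is aimed at computational neuroscientists studying closed-loop
stimulation protocols (in silico counterparts of the classic in-vitro
"train a dish" experiments) and at anyone who wants a fast, reproducible
Izhikevich/STDP/STP simulator with tidy outputs.

## The model in brief

Neurons follow the Izhikevich dynamics `v' = 0.04v² + 5v + 140 − u + I`,
`u' = a(bv − u)` with spike-and-reset at 30 mV, at a 1 ms step; regular-spiking
cells are excitatory, fast-spiking cells inhibitory (80/20 in a 100-neuron
network). Input per neuron and millisecond sums synaptic drive from the
previous step's spikes, external 1000 Hz stimulation channels, and Gaussian
noise. Excitatory-to-excitatory synapses evolve by additive pair-based STDP,

    Δw(s) = ±A·exp(−|s|/τ),  A = 0.1, τ = 20 ms,  w ∈ [0, w_max],

plus a global multiplicative decay `w ← (1−μ)w` (μ = 5×10⁻⁷) in the
100-neuron experiments. Tsodyks–Markram-style short-term plasticity
(`w* = u·x·w`, U = 0.2, τ_d = 200 ms, τ_f = 600 ms) optionally suppresses
network-wide bursts. Training protocols implement the stop condition (remove
stimulation when ≥ n neurons of output zone A spike in a 1 ms bin, optionally
while zone B stays below threshold in the same bin) and the stimulus condition
(punish zone-B activity with 10 ms of network-wide stimulation). An embodied
variant couples the network to a simulated robot with two distance sensors
that learn wall avoidance. The methods vignette
(`vignettes/lsa-methods.Rmd`) documents every equation, parameter and design
choice.

## Worked example

```r
library(lsanet)

cfg <- lsa_config("selective_learning")   # 100 neurons, e = 1 mV, stop 4/4
run <- simulate_training(cfg, seed = 42)
run
#> <lsa_run> preset 'selective_learning', seed 42, 400 s simulated
#>   trials: 202 (0 timed out)
#>   learned at 133.1 s; attained reaction time 235 ms

head(tidy(run), 5)                        # one row per stimulation trial
#>   trial onset_ms reaction_time_ms timed_out delay_ms
#> 1     1        0              462 FALSE        1985
#> 2     2     2447               43 FALSE        1282
#> 3     3     3772               91 FALSE        1300
#> 4     4     5163              986 FALSE        1850
#> 5     5     7999               34 FALSE        1510
```

The network was stimulated 202 times in 400 simulated seconds. Reaction times
(stimulation onset to the first millisecond with ≥ 4 spikes in output zone A
and < 4 in zone B) start erratic and fall; from 133.1 s onward they stay below
the 4000 ms learning criterion, averaging 235 ms — the network has learned to
shut the stimulation off. `autoplot(run)` draws the learning curve,
`glance(run)` returns the one-row summary, and `write_results(run, dir)`
writes `trials.csv`, `metrics.json`, the raster and the config echo.

Other entry points: `simulate_robot("closed", seed = 1)` runs the embodied
wall-avoidance task (`wall_proximity()`, `mean_stimulation()`, `autoplot()`
summarize it), `run_sweep()` maps learnability over connectivity,
`lsa_config()` exposes every preset (`chain3_reinforce`, `chain3_prune`,
`sparse_steering`, `stp_selective`, ...), and `inst/cli/lsanet.R` is a thin
command-line wrapper over the same functions.

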