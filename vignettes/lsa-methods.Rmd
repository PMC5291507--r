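---
title: "Learning by stimulation avoidance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning by stimulation avoidance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsanet)
```

## The principle

Learning by stimulation avoidance (LSA) is an emergent property of spiking
networks equipped with spike-timing-dependent plasticity (STDP) and coupled to
an environment through external stimulation: firing patterns whose occurrence
*removes* an ongoing stimulation are strengthened, and patterns that *trigger*
stimulation are weakened. No reward signal or value function is involved —
the only learning rule is local, pairwise STDP; the environmental contingency
(when stimulation starts and stops) does the steering. `lsanet` simulates this
loop at 1 ms resolution and reproduces its signature phenomena: selective
learning of an output pattern, synaptic reinforcement and pruning in a minimal
three-neuron circuit, firing-rate steering, and embodied wall-avoidance
learning in a simulated robot.

## Neuron model

Neurons follow the two-variable quadratic integrate-and-fire dynamics

$$v' = 0.04 v^2 + 5v + 140 - u + I, \qquad u' = a(bv - u),$$

with a spike recorded when $v \ge 30$ mV, followed by the reset $v \leftarrow
c$, $u \leftarrow u + d$. Excitatory neurons are regular spiking
($a=0.02, b=0.2, c=-65, d=8$), inhibitory neurons fast spiking
($a=0.1, b=0.2, c=-65, d=2$). Input sums three terms per neuron and
millisecond: synaptic input from the previous step's presynaptic spikes,
external stimulation (a 1000 Hz channel adds its amplitude every step while
active), and fresh zero-mean Gaussian noise of standard deviation `sigma`.

Numerical choices:

* **Integration.** Within each 1 ms step the voltage advances in two 0.5 ms
  sub-steps (the model's published scheme) and the recovery variable once;
  `integrator = "euler"` selects a single full step instead. Spikes at step
  $t$ are delivered as input at $t+1$ (one-step synaptic latency, no axonal
  delays), which keeps each step explicit.
* **Threshold handling.** The threshold test runs after the sub-steps; all
  neurons crossing in the same step spike simultaneously. Once a sub-step
  crosses threshold the remaining sub-step is skipped, and the recovery update
  sees $\min(v, 30)$ — the model caps spikes at +30 mV, and without these two
  guards the quadratic term amplifies the overshoot at strong drive.
* **Hyperpolarization floor.** $v$ is floored at −90 mV (a reversal-potential-
  like bound). Extreme inhibitory volleys in high-weight sparse networks can
  otherwise push $v$ so far negative that the quadratic term catapults it
  upward and the explicit scheme diverges.
* **Discretization bias.** Against a 0.01 ms reference integration, the 1 ms
  grid tracks regular-spiking rates within ±1 spike/s up to ~20 Hz. Beyond
  that the count is biased low (each spike consumes a full step): roughly 8%
  at $I = 20$ mV for regular spiking and up to ~35% for fast-spiking cells
  near their grid limit. Network-level phenomena are robust to this bias, but
  absolute rates at high drive should be read with it in mind.

## Plasticity

**STDP** applies only between excitatory neurons. For a synapse $a \to b$ and
relative spike timing $s = t_b - t_a$,

$$\Delta w(s) = \begin{cases} A e^{-s/\tau} & s > 0 \\ -A e^{s/\tau} & s < 0
\\ 0 & s = 0, \end{cases}$$

with $A = 0.1$ and $\tau = 20$ ms. Pairing is nearest-spike: each new spike
pairs once with the counterpart neuron's most recent spike, both directed
synapses of the pair are updated, and pairs further apart than $5\tau =
100$ ms are skipped (the update would be below $10^{-3} \cdot A$). Exactly
simultaneous spikes contribute nothing — the pair rule is discontinuous at
$s = 0$ and neither branch is privileged. Updated weights clip to
$[0, w_{max}]$; the cap is per-experiment configuration (10 for the fully
connected selective-learning network, 50 for sparse high-weight networks, 20
for the short-term-plasticity experiments), never hard-coded.

**Decay.** All weights shrink multiplicatively, $w \leftarrow (1-\mu)w$ with
$\mu = 5 \times 10^{-7}$ per iteration, in the 100-neuron experiments;
three-neuron and robot runs leave it off. Whether decay should touch
non-plastic (inhibitory) weights is ambiguous in the source material — the
default applies it to all weights, `decay_scope = "plastic"` restricts it to
excitatory-excitatory synapses, and tests pin only the excitatory behaviour.
The engine tracks the uniform factor lazily as a scalar and folds it into the
matrix on output, which is algebraically exact.

**Short-term plasticity (STP).** Each excitatory neuron carries a depression
variable $x$ and facilitation variable $u$,

$$\frac{dx}{dt} = \frac{1-x}{\tau_d} - u\,x\,f, \qquad
  \frac{du}{dt} = \frac{U-u}{\tau_f} + U(1-u)\,f,$$

with $U = 0.2$, $\tau_d = 200$ ms, $\tau_f = 600$ ms and $f$ the spike
indicator, advanced by the same 1 ms Euler clock (both derivatives evaluated
at the step-start state). Outgoing weights of excitatory neurons are modulated
as $w^* = u\,x\,w$; at rest $w^* = 0.2\,w$, and because depression outpaces
facilitation under sustained firing, neurons that fire too often are
attenuated — this is what suppresses network-wide bursts in the fully
connected 100-neuron network.

## Topologies, zones and initial weights

Three topologies: fully connected (no self-connections), sparse fixed
out-degree (each neuron draws $M$ targets *with replacement*, duplicates
collapse), and the three-neuron chain. Initial weights are uniform —
magnitude $U(0, 5)$ (or $U(0, 10)$ for the sparse experiments), positive for
excitatory and negative for inhibitory neurons — or, for the connectivity
sweep, $5 + \omega$ with $\omega \sim U(-v, v)$, clipped at zero to preserve
the sign.

Stimulation and readout zones are disjoint random subsets of the excitatory
population (10 neurons each in every 100-neuron experiment). With
`forbid_direct_io` every weight from an input zone to an output zone is zeroed
and masked non-existent for the whole run, so learning must recruit indirect
pathways. For the three-neuron circuits the zones are pinned: neuron 1 is the
input, neuron 3 the output, neuron 2 hidden.

The three-neuron presets use fixed initial weights rather than random draws
(the experiments are defined by their initial states): reinforcement starts
the direct weight at 2 with all other weights at 3 — demonstrating that the
direct connection overtakes despite starting lower — the indirect variant
freezes the direct weight at 0, and the pruning variant starts all weights
at 3. Per-seed variability then comes only from the noise stream. The
stimulation amplitude for these circuits is not printed in the source
material; 10 mV is used so that a single externally driven neuron fires
reliably above the 3 mV noise floor (at 1 mV it would barely fire and no
weight dynamics would emerge).

## Protocols

A training run repeats two steps: stimulate the input zone at 1000 Hz; remove
the stimulation as soon as the desired output occurs. Concretely, per 1 ms
bin:

* **Stop condition** — at least `stop_thr_a` spikes in output zone A and
  (when the clause is set) fewer than `stop_thr_b` spikes in output zone B,
  *in the same bin*. Meeting it ends the trial; the reaction time is the
  delay from stimulation onset to that bin. An undetected output times out
  after 10 s of stimulation. Either way the next trial starts after a uniform
  integer delay of 1000–2000 ms.
* **Stimulus condition** (punishment) — at least `stimulus_thr` spikes in
  output zone B trigger 10 ms of stimulation of every excitatory neuron
  outside zone B (input-zone neurons included; they are excitatory and not
  excluded). A trigger during a pending window restarts the window. The
  punishment amplitude equals the experiment's stimulation amplitude; no
  separate value is printed in the source material.

A network has *learned* at the start of the earliest trial from which every
subsequent reaction time stays below 4000 ms; the learning time is the
elapsed simulated time at that trial's onset, and the attained reaction time
averages the reaction times from that trial onward (the averaging window is
not specified in the source material; the whole post-learning suffix is
used). Success means learning within the 400 s budget. Learnability — used
by the connectivity sweep — is the output zone's mean per-neuron rate over
the last 100 s minus the first 100 s of a 500 s run. The sweep uses the
stop condition only, with threshold 1 (as in the sparse steering experiment;
the stricter 4/4 thresholds belong to the STP experiments).

Preset parameter sets:

| preset | topology | $\sigma$ | $e$ | $w_{max}$ | $\mu$ | conditions |
|---|---|---|---|---|---|---|
| `selective_learning` | full 80E/20I | 3 | 1 | 10 | 5e-7 | stop 4/4 |
| `sparse_steering` | sparse M=20 | 5 | 10 | 50 | 5e-7 | stop 1 + stimulus 1 |
| `stp_selective` | full + STP | 3 | 10 | 20 | 5e-7 | stop 4/4 + stimulus 1, no direct I/O |
| `chain3_*` | 3 neurons | 3 | 10 | 10 | 0 | per variant |
| `sweep` | sparse M | 5 | 10 | 50 | 5e-7 | stop 1 |

## The embodied task

A circular robot (radius 25 px, speed 1 px/ms) moves in a 1000 px square
arena. Two distance sensors point at $\pm\pi/4$ from the heading with an
80 px range; each drives one 10-neuron input zone with
$\text{sensitivity}/\text{distance}$ mV per millisecond. Spikes in two
10-neuron output zones steer the robot by $\pm\pi/6$ per spike
(non-differential); it then advances 1 px along the new heading, and on wall
contact the position clamps component-wise to the arena (heading unchanged).
The controller network is the fully connected STP configuration without decay
and without zeroed input-output weights (that manipulation belongs to the
non-embodied STP experiment).

Sensor distances are **hull-based**: the ray length from the centre minus the
robot radius, clamped at 1 px. This was a genuinely open design point, and
the centre-based alternative turns out to be inconsistent with the task: the
centre can never be closer than 25 px to a wall, capping the input at
sensitivity/25 ≈ 0.3 mV against a 3 mV noise floor — no learning signal
survives, and the closed-loop stimulation averages reported for this
experiment become unreachable. With hull distances the input spans its full
range up to the sensitivity at wall contact. The wall-proximity metric uses
the same convention (hull within 80 px of a wall). Centre-based readings
remain available (`sense(radius = 0)`).

The stimulation ledger counts amplitudes per sensor channel: an open-loop
control at 8 mV per channel pays exactly 16 mV/ms regardless of pose. The
matched-stimulation control applies a constant per-channel amplitude equal to
half the mean per-ms total delivered in matched closed-loop runs.

## Randomness and reproducibility

One master seed fans out to named substreams (topology, zones, run noise +
inter-trial delays, robot pose) via `seed_for()`, so changing one stochastic
component leaves the others bit-reproducible. Runs with equal seeds are
byte-identical, and a run can be snapshotted and resumed exactly (`resume()`)
provided the R session's RNG state is carried over. A pure-R reference engine
(`engine = "r"`), composed from the exported step primitives, reproduces the
compiled engine's spike raster exactly — including the noise stream — and is
used in the tests to validate the compiled loop on small fixtures.

## What the simulations do and do not show

The generator emulates the study conditions: seeded random networks of
Izhikevich neurons with the parameter sets above, driven by the closed-loop
protocols. It does not emulate biological cultures: there are no conduction
delays, no synaptic time constants (input arrives as 1 ms pulses), two cell
classes only, no homeostasis, and the noise is white Gaussian rather than
spontaneous miniature activity. Passing tests therefore demonstrate the
*mechanism* — that STDP plus stimulation contingencies produce avoidance
learning, pruning and steering in this model class — not a quantitative match
to any in-vitro preparation.

Known limitations worth keeping in mind:

* High-rate spike counts are biased low by the 1 ms grid (see above).
* Under the documented parameterization, constant open-loop stimulation of
  the robot's input zones yields modest output-zone activity (~0.4
  Hz/neuron), so the open-loop robot steers little and hugs the walls more
  than the reported comparison curves; the closed-versus-open ordering, which
  is the substantive claim, reproduces robustly.
* The closed-loop robot's average delivered stimulation depends on the exact
  geometry of its wall-pressed poses and is sensitive to the stuck-state
  details of the collision model.

## Problem sizes used by the test suite

The suite runs the selective-learning experiment at 10 seeds (full 400 s
budget each), the control at 10, the three-neuron circuits at 20 seeds, the
steering comparison at 20 seeds x 500 s, the sweep on a 3 x 2 grid at 5
repetitions, and the robot comparison at 10 seeds x 1000 s plus 5 matched
controls; `scripts/acceptance.R` runs the full 20-seed versions of the
headline experiments. These sizes keep each statistical check's power close
to the original design while the whole suite stays re-runnable in minutes.
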