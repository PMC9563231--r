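---
title: "A spiking neuronal network agent for cart-pole balancing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking neuronal network agent for cart-pole balancing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spikecart` simulates a small three-layer spiking neuronal network that
learns to balance the classic cart-pole, and implements two complete
training regimes operating at different timescales: reward-modulated
spike-timing-dependent plasticity (STDP-RL) with a hand-crafted critic and
synaptic homeostasis, and a multiplicative evolutionary strategy over the
plastic synaptic weights. This vignette documents the model, its
assumptions, the tunable parameters, and the design choices made where the
design was genuinely open.

## The neuron model

Each cell is a reduced, event-driven integrate-and-fire unit. Nothing is
integrated on a clock: every state variable decays exponentially between
events, so the state is updated lazily whenever a synaptic event arrives.
The membrane potential is a derived quantity

$$V_m = V_{rest} + V_{AM2} + V_{NM2} - V_{GA} - V_{GA2} - V_{AHP},$$

where the four $V_{syn}$ are per-channel synaptic voltages (AMPA, NMDA,
somatic GABAA, dendritic GABAA, with decay constants 20, 300, 10, 20 ms and
reversal potentials 0, 0, -80, -80 mV) and $V_{AHP}$ is an
after-hyperpolarization that increments by $\Delta V_{AHP}$ at every spike.
Inhibitory channels enter with a negative sign so that all stored synaptic
weights are non-negative. A synaptic event of weight $W$ changes its
channel by the voltage-dependent step

$$dV = W\left(1 - \frac{V_m - V_{rest}}{E_{syn} - V_{rest}}\right),$$

with the reversal potential taken relative to rest. Two consequences anchor
the unit tests: an excitatory event at rest depolarizes by exactly $W$, and
the step vanishes when the membrane sits at the channel's reversal.

A cell fires when an event pushes $V_m$ to or above the instantaneous
threshold, provided $V_m$ does not exceed the depolarization-blockade
voltage $V_{block}$ (runaway excitation silences rather than accelerates a
cell) and the absolute refractory period $\tau_{AR}$ has elapsed. A spike
raises the threshold by $W_{RR}(V_{block} - V_{thresh})$ — a relative
refractory period that decays back with $\tau_{RR}$ — increments
$V_{AHP}$, and resets the synaptic voltages to zero. The reset is our
choice where the source description is silent; it prevents immediate
re-fire from residual depolarization and matches the convention of the
reduced models this cell descends from. Fire checks happen only at event
arrival times: between events the membrane only decays, so no threshold
crossing can be missed. Three cell classes are parameterized (excitatory,
fast-spiking inhibitory, low-threshold inhibitory); see `cell_types()`.

Correctness is established two independent ways: a pure-R single-neuron
implementation (`neuron_state()`, `decay_to()`, `deliver_event()`) is
checked against the C++ engine event-for-event, and both are checked
against a dense clock-driven oracle that applies per-tick exponential
relaxation at 1 µs resolution (`neuron_trajectory_clock()`), agreeing to
better than $10^{-6}$ mV over a thousand random event sequences.

## The network

`build_network()` constructs 200 neurons in three layers: 80 sensory
excitatory neurons (ES, four 20-neuron groups, one per state variable), an
association layer (40 EA excitatory, 10 + 10 inhibitory), and a motor layer
(20 + 20 excitatory neurons voting for left and right, 10 + 10 inhibitory).
Activity propagates strictly forward ES → EA → EM, with inhibition keeping
each layer from saturating.

The connectivity table (`default_connectivity()`) gives each pathway a
*convergence* — interpreted as the number of distinct presynaptic sources
wired into each postsynaptic neuron, the native meaning in the simulators
this architecture comes from. We note two reasons this in-degree reading is
the right one even though "convergence" is sometimes described as a count
of outgoing targets: several excitatory-to-inhibitory rows specify a
convergence (15 or 16) larger than their 10-neuron target population, which
is impossible as an out-degree without replacement; and fixed in-degree
equalizes the summed synaptic input of every motor neuron, which is exactly
what keeps untrained networks at random-policy performance regardless of
the wiring seed. We verified the latter empirically: with out-degree
sampling, untrained performance ranged from 16 to 28 steps/episode across
ten wiring seeds (a consequence of unequal left/right motor drive), while
with in-degree sampling all ten land between 19 and 30 with both canonical
seeds near the random-policy level of ~22.

Excitatory pathways carry paired AMPA + NMDA synapses from the same
sources. Only the AMPA synapses of ES→EA and EA→EM are plastic; their
weights, in a fixed build order, form the *genome* (1000 + 800 = 1800
entries) that both training algorithms manipulate. Somatic delays are
drawn Uniform(1.8, 2.2) ms, dendritic GABAA delays Uniform(3, 12) ms.
Wiring and delays come from independent RNG substreams of the wiring seed,
so a seed pins the network byte-for-byte; target sampling is without
replacement (with replacement would create duplicate synapses the
connectivity table gives no license for).

## Sensory encoding, stimulation, and motor decoding

Each state variable is place-coded by one 20-neuron group. The bins are the
twenty equal-probability slices of a zero-mean Gaussian
(`build_receptive_fields()`): boundaries at $\Phi^{-1}(k/20)\sigma$, narrow
fields near balance where precision matters, broad fields at the
periphery. Neurons 1–10 cover negative values with neuron 1 the most
negative — chosen so the code is globally monotone — and a value of
exactly 0 maps to neuron 11, the first positive-side neuron. The default
widths ($\sigma$ = 0.5, 0.5, 0.05, 0.4 for position, velocity, angle,
angular velocity) are calibrated so random-policy rollouts occupy most
bins; `estimate_sigmas()` recomputes them empirically from rollouts.

At each 50 ms agent step exactly one neuron per group is selected and
receives external AMPA stimulation — the only external input to the
network. The stimulation weight (35) is chosen to exceed the 25 mV
rest-to-threshold gap even under accumulated after-hyperpolarization while
keeping the stimulated cell below its depolarization block, so each
selected neuron fires reliably, once per event.

Stimulation is delivered as a short two-event burst (offsets 0 and 15 ms,
`stimulation_burst()`). This is a deliberate excitability calibration, and
the one place where we depart from a single spike per activated neuron:
with the published synaptic weights and in-degrees, four lone sensory
spikes cannot depolarize association neurons (which need roughly three
coincident 10 mV inputs out of only four active sources) to threshold, so
the downstream network stays silent — no motor spikes, no spike pairs, no
learning signal of any kind. The original implementation rests on a richer
NEURON-based cell with burst dynamics that the reduced model deliberately
omits; the burst restores the intended operating point at the population
level. It was calibrated against two published operating conditions only —
baseline layer rates in the 2–20 Hz band near the homeostatic set points
(achieved: EA ≈ 3.9 Hz, EM ≈ 4.1 Hz against targets of 5.5 and 6.0 Hz),
and untrained networks performing at random-policy level — and then
frozen.

Decoding is winner-take-all: whichever motor subpopulation spikes more in
the window dictates the action; a tie (including total silence) raises the
`no_move` flag and draws the action uniformly. Ties matter: the critic
punishes them explicitly.

## The critic

The critic converts consecutive game states into a scalar in $[-1, 1]$
from a per-state loss $\ell(t) = \mathrm{ang}(t)^2 +
\eta_{angvel}\,\mathrm{angvel}(t)^2$. The reward cases apply in strict
order: a previous state already near balance ($\ell < 10^{-2}$) yields 0
regardless of anything else, including a simultaneous no-move — the
top-down reading of the case structure; a no-move yields
$-max\_reward/\eta_{positivity}$; reaching balance yields the positive
counterpart; otherwise the reward is the loss decrease. Positive rewards
are then boosted by $\eta_{positivity}$ (early training is dominated by
punishment; without the boost weights collapse toward zero), scaled by
`gain`, and clamped to $\pm 1$. The tuned values of $\eta_{positivity}$,
$\eta_{angvel}$ and `gain` were never published; the package defaults (2,
0.5, 5) are documented defaults exposed in `critic_params()`, not claims
about the original experiments.

## STDP-RL

When a postsynaptic spike follows a presynaptic spike within `windhebb`
(default 20 ms, closed boundary), the synapse acquires an eligibility tag
that lives for `lenhebb` (default 1000 ms, in line with reported
eligibility windows of one to a few seconds). Because the eligibility
trace enters the update with exponent one, the weight change at delivery is
constant in tag age: every live tag changes by
$\Delta w = hebbwt \cdot critic \cdot s \cdot b$, floored at zero.
Re-tagging refreshes expiry rather than stacking — with constant-magnitude
updates, stacking would be indistinguishable anyway, and refreshing bounds
memory. Tags are cleared at episode boundaries; carrying credit across
independently initialized episodes would mis-assign reward.

The factor $s$ implements targeted delivery. In `non_targeted` mode all
motor-pathway tags receive the critic equally. `targeted_main` restricts
delivery to EA→EM synapses onto the subpopulation that generated the
action; `targeted_both` (the default, which the original hyperparameter
exploration favored) additionally sends sign-flipped, attenuated
reinforcement to the opposite subpopulation. ES→EA synapses — one synapse
upstream of the action — receive the critic attenuated by
`non_motor_attenuation` whenever `non_motor_rl` is set, in every mode; we
read the non-motor toggle as orthogonal to the targeting mode since it
addresses a different part of the circuit. The attenuation factors (0.5)
are again documented defaults; the tuned values are unavailable.

The factor $b$ is output balancing (below). Training can be phased
(`phases` argument) to mirror protocols that change hyperparameters after
fixed simulated durations (500 s, 2000 s, 2000 s); the defaults run a
single phase.

## Synaptic homeostasis

Three mechanisms run only while STDP-RL is active and are inert during
evolutionary training and frozen evaluation:

- **Input balancing** (every 25 agent steps): each neuron's incoming
  plastic weights are rescaled by a common factor so their sum equals its
  reception target — synaptic competition under a conserved budget. After
  every call, each touched neuron's total matches its target to within
  $10^{-9}$ (a test asserts this).
- **Output balancing** (at every critic delivery): with transmission ratio
  $\rho = \text{initial total} / \text{current total}$ of the presynaptic
  neuron, rewards scale by $\mathrm{clamp}(\rho, 0.1, 2)$ and punishments
  by $\mathrm{clamp}(1/\rho, 0.1, 2)$. The exact formula was never stated;
  this ratio-with-reciprocal form reproduces every qualitative statement
  about it (grown outputs get weaker rewards and stronger punishments,
  shrunken outputs the reverse, clamped at 0.1 down and 2.0 up) and is
  continuous at $\rho = 1$. Factors are computed from totals as they stood
  when the critic arrived, then all changes apply at once.
- **Homeostatic gain control** (every 75 steps): population rates are
  measured over the trailing 500 steps (25 s) and each neuron's reception
  *target* — not its weights — drifts by ±0.01% toward the set points
  (5.5 Hz for EA, 6.0 Hz for EM). Targets are per-neuron, seeded from each
  neuron's build-time total, so heterogeneous totals stay heterogeneous.

## The evolutionary strategy

The genome $w$ evolves by multiplicative perturbation: each iteration
samples $P$ (default 10) standard-normal rows $\epsilon_j$, evaluates
$w(1 + \sigma\epsilon_j)$ with $\sigma = 0.1$ on $X$ (default 5) fresh
episodes each, takes mean steps survived as fitness $F_j$, normalizes
$N = (F - \bar F)/\mathrm{std}(F)$ (population standard deviation; a
zero-variance vector yields a no-op update rather than a division by
zero), and updates

$$w \leftarrow w\,\bigl(1 + \alpha\,\sigma\,\epsilon^{\top} N / P\bigr),$$

floored at zero — the multiplicative form keeps the search relative to each
weight's scale and the floor keeps weights valid, since the tails of the
update are not sign-safe. Episode start states during training are fresh
random draws from per-(iteration, perturbation) substreams, so evaluating
the perturbations in any order gives the same update. Plasticity and
normalization are fully disabled throughout. The iteration budget is a
config knob (1500 by default, 1600 for the longer published protocol;
both lengths were used in the original experiments).

## Datasets and circuit dissection

`episode_datasets()` derives two disjoint fixed sets of 100 episode start
states from a master seed — validation (model selection) and testing
(reporting). `evaluate_frozen()` plays them with everything frozen.

`all_inputs_sweep()` enumerates sensory quadruples ($20^4$ = 160,000 in
lexicographic order; a `stride` subsamples) against an isolated network,
with 150 ms blanks between activations; the blank length is checked, not
assumed — residual spikes in a blank are counted and reported.
`action_selectivity()` gives each (activated sensory neuron, network
neuron) pair a signed participation value: $+p_L$ if the neuron spikes at
least as often during left moves as right moves under that activation
(ties break toward left, matching the worked examples that anchor the
tests), else $-p_R$; a neuron counts as active in a record if it spiked at
least once in the response window. `sensory_motor_map()` marginalizes the
sweep to $P(\text{left}/\text{stay}/\text{right})$ over every pair of
sensory variables; "stay" is a winner-take-all tie.

## The environment

The cart-pole follows the published CartPole-v1 definition: gravity 9.8,
cart mass 1.0, pole mass 0.1, half-length 0.5, force ±10, explicit Euler
at 0.02 s, reset states Uniform(−0.05, 0.05), termination at |position| >
2.4 or |angle| > 12° (the prose description of a 15° bound is supported
via `cartpole_params(angle_limit_deg = 15)`; the v1 value is the default
since the environment is named explicitly), 500-step cap. One agent step
is one environment step; the 50 ms is simulated neural time per step, not
physics time. The one-step dynamics are pinned to an independent
closed-form derivation at $10^{-10}$, and mirror symmetry (negate the
state, swap the actions) is property-tested.

## Numerical and reproducibility choices

Event ordering is deterministic: simultaneous events process in insertion
order. All randomness flows from named substreams (`substream_seed()`) —
wiring, delays, episode resets, tie-breaks, evolution noise — so changing
one never perturbs another, and tie-breaks inside the C++ episode runner
use a private xorshift stream seeded per episode. Weight floors apply
after every STDP and evolutionary update. Time regression in the neuron
(an event arriving before the state's last update) is treated as a
scheduling bug and raises an error rather than being clamped.

## Problem sizes used by the test suite

The suite verifies the training claims at deliberately reduced scale,
chosen as the smallest runs that exercise the full mechanism: the
evolutionary check runs to the 400-step fitness level (reached around
iteration 250 of the 500-iteration budget) rather than the full
1,600-iteration protocol whose end state (test median 500) we also
observed when running longer; the STDP-RL check trains for 2,000 simulated
seconds (40,000 agent steps) and asserts a statistically significant
improvement of the best 100-episode training window over the untrained
baseline, rather than reproducing multi-hour 25,000 s multi-seed
statistics; sweeps use strides of a few hundred instead of the full
160,000 combinations.

## Known limitations

The reduced neuron omits the voltage-sensitive NMDA nonlinearity and
intrinsic bursting of its NEURON-based ancestor; the two-event stimulation
burst compensates at the population level but is not a mechanistic model
of those currents. The NMDA channel shares the AMPA driving-force rule,
differing only in time constant and weight. Tuned hyperparameter values
for the critic and STDP-RL (published only in an unavailable supplement)
are replaced by documented defaults, so STDP-RL learning magnitudes are
indicative rather than reproductions. Synthetic episode seeds stand in for
the original environment seeds, which were never published; fixtures are
generated, never shipped. Structural plasticity, inhibitory plasticity and
delay evolution are out of scope.
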