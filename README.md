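# spikecart

Spiking neuronal network agents for the cart-pole control task.

`spikecart` is for computational neuroscientists who want a compact,
fully-seeded testbed for comparing biologically inspired learning rules on
a closed sensorimotor loop. It simulates a three-layer
excitatory/inhibitory spiking network — 80 place-coded sensory neurons,
an association layer, and two 20-neuron motor populations that vote
winner-take-all for pushing the cart left or right every 50 ms — and
trains it with two complete regimes operating at different timescales:

- **STDP-RL** — reward-modulated spike-timing-dependent plasticity.
  Causal pre-before-post spike pairs tag synapses with eligibility traces;
  a hand-crafted critic
  `critic(t) = clamp(f(loss(t-1) - loss(t)) * gain, -1, 1)` with
  `loss = ang² + η·angvel²` converts each transition into reward or
  punishment delivered to the tagged synapses (optionally targeted to the
  motor subpopulation that acted), under three homeostatic normalization
  mechanisms (input balancing, output balancing, homeostatic gain
  control).
- **EVOL** — an evolutionary strategy over the plastic-weight genome `w`:
  sample multiplicative perturbations `w(1 + σε_j)`, score each by mean
  episode length, normalize fitness `N`, and update
  `w ← w(1 + ασ εᵀN / P)` with weights floored at zero.

Neurons are event-driven reduced integrate-and-fire units with
adaptation, relative and absolute refractoriness, and depolarization
block; four synaptic channels (AMPA, NMDA, somatic and dendritic GABAA)
decay exponentially between events. The cart-pole environment is a
deterministic, seedable re-implementation of the CartPole-v1 dynamics.
Post-training, circuit-dissection tools enumerate all 20⁴ sensory inputs
to map each neuron's action selectivity and the network's sensory-motor
associations.

## Worked example

```r
library(spikecart)

net <- build_network(6)        # seeded wiring; identical seed, identical net
net
#> <snn_network> wiring seed 6
#>   200 neurons in 8 populations; 5600 synapses, 1800 plastic

ds <- episode_datasets(1)      # 100 fixed validation + 100 fixed test episodes
ev <- evaluate_frozen(net, ds$testing)
ev
#> <frozen_eval> 100 episodes; mean 22.72 median 19.5 steps/episode
```

An untrained network survives ~22 steps per episode — statistically
indistinguishable from choosing actions at random, because every motor
neuron receives the same summed input by construction. Training with the
evolutionary strategy drives it to the 500-step cap:

```r
fit <- run_evol(net, evol_params(iterations = 500), seed = 1,
                target_fitness = 400)
tail(fit$log, 1)["mean"]
#> # A tibble: 1 × 1
#>    mean
#>   <dbl>
#> 1  402.     # reached at iteration 286

evaluate_frozen(net, ds$testing, genome = fit$genome)
#> <frozen_eval> 100 episodes; mean 446.95 median 500 steps/episode
```

Mean iteration fitness crosses 400 steps within roughly 250–500
iterations, and the evolved genome holds the pole for the full 500-step
cap on most fixed test episodes. A short STDP-RL run shows the
individual-timescale counterpart:

```r
stdp <- run_stdp_training(net, duration_s = 2000, seed = 1)
max(moving_average(stdp$episodes$steps, 100))
#> [1] 38.8
```

— the 100-episode moving average climbs well above the untrained
baseline within 2,000 simulated seconds (the longer the run, the higher
the plateau; performance remains well short of the evolutionary optimum,
which is the central comparison the package supports).

Dissecting a frozen circuit:

```r
sw <- all_inputs_sweep(net, stride = 400, genome = fit$genome)
sel <- action_selectivity(sw)      # 80 x 200 signed participation map
maps <- sensory_motor_map(sw)      # P(left/stay/right) per variable pair
```

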