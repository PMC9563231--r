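#' Create a fresh single-neuron state
#'
#' The neuron is an event-driven, lazily-decayed unit: between events every
#' state variable relaxes exponentially, so the full state only needs
#' updating when an event arrives. The membrane potential is the derived
#' quantity
#' \deqn{V_m = V_{rest} + V_{AM2} + V_{NM2} - V_{GA} - V_{GA2} - V_{AHP}.}
#'
#' @param cell_type One of `"E"`, `"I"`, `"IL"` (see [cell_types()]).
#' @return A `neuron_state` object (a list with per-channel synaptic
#'   voltages, after-hyperpolarization, current threshold, bookkeeping times
#'   and recorded spike times).
#' @seealso [decay_to()], [deliver_event()], [membrane_potential()]
#' @export
#' @examples
#' st <- neuron_state("E")
#' membrane_potential(st)   # -65 at rest
neuron_state <- function(cell_type = c("E", "I", "IL")) {
  cell_type <- match.arg(cell_type)
  p <- cell_params_row(cell_type)
  structure(list(
    cell_type = cell_type,
    params = p,
    v_syn = c(AM2 = 0, NM2 = 0, GA = 0, GA2 = 0),
    v_ahp = 0,
    v_thresh = p$v_thresh,
    last_update_time = 0,
    refractory_until = -Inf,
    spike_times = numeric(0)
  ), class = "neuron_state")
}

#' Membrane potential of a neuron state
#'
#' @param state A [neuron_state()].
#' @return Membrane voltage in mV at the state's `last_update_time`.
#' @export
membrane_potential <- function(state) {
  ch <- synapse_channels()
  state$params$v_rest + sum(ch$sign * state$v_syn[ch$kind]) - state$v_ahp
}

#' Relax a neuron state forward in time
#'
#' Applies the closed-form exponential decays: each synaptic voltage decays
#' toward 0 with its channel time constant, the after-hyperpolarization
#' decays with `tau_ahp`, and the instantaneous threshold relaxes toward its
#' baseline with the relative-refractory time constant. No events are
#' processed and no spikes can occur (between events the membrane only
#' decays, so it cannot cross threshold upward).
#'
#' @param state A [neuron_state()].
#' @param t Target time in ms; must not precede `state$last_update_time`.
#' @return The updated `neuron_state`.
#' @export
#' @examples
#' st <- neuron_state("E")
#' st$v_syn[["AM2"]] <- 10
#' decay_to(st, 20)$v_syn[["AM2"]]   # 10 / e
decay_to <- function(state, t) {
  dt <- t - state$last_update_time
  if (dt < 0) stop("time regression: t precedes last_update_time")
  if (dt > 0) {
    ch <- synapse_channels()
    state$v_syn <- state$v_syn[ch$kind] * exp(-dt / ch$tau_decay)
    state$v_ahp <- state$v_ahp * exp(-dt / state$params$tau_ahp)
    state$v_thresh <- state$params$v_thresh +
      (state$v_thresh - state$params$v_thresh) * exp(-dt / state$params$tau_rel_refrac)
    state$last_update_time <- t
  }
  state
}

#' Deliver a synaptic event to a neuron
#'
#' Decays the state to `t`, then applies the voltage-dependent step
#' \deqn{dV = W (1 - (V_m - V_{rest}) / (E_{syn} - V_{rest})),}
#' where the reversal potential is taken relative to rest, so an excitatory
#' event at rest depolarizes by exactly `W` and the step vanishes when the
#' membrane sits at the channel's reversal potential. After the step the
#' fire condition is checked: the neuron spikes iff `v_m >= v_thresh`
#' (current, relative-refractory-elevated threshold), `v_m <= v_block`
#' (depolarization block), and the absolute refractory period has elapsed.
#' On a spike the spike time is recorded, the after-hyperpolarization is
#' incremented, the threshold is raised by `w_rel_refrac * (v_block -
#' v_thresh)`, the absolute refractory window starts, and all synaptic
#' voltages reset to 0.
#'
#' @param state A [neuron_state()].
#' @param channel Channel kind: `"AM2"`, `"NM2"`, `"GA"` or `"GA2"`.
#' @param weight Non-negative synaptic weight.
#' @param t Event time in ms.
#' @return A list with elements `state` (updated) and `fired` (logical).
#' @export
#' @examples
#' out <- deliver_event(neuron_state("E"), "AM2", 10, 1)
#' membrane_potential(out$state)   # -55, no spike
deliver_event <- function(state, channel, weight, t) {
  if (weight < 0) stop("negative synaptic weight")
  ch <- synapse_channels()
  if (!channel %in% ch$kind) stop("unknown synapse channel kind: ", channel)
  state <- decay_to(state, t)
  p <- state$params
  vm <- membrane_potential(state)
  e_syn <- ch$e_syn[ch$kind == channel]
  dv <- weight * (1 - (vm - p$v_rest) / (e_syn - p$v_rest))
  state$v_syn[[channel]] <- max(0, state$v_syn[[channel]] + dv)
  vm <- membrane_potential(state)
  fired <- vm >= state$v_thresh && vm <= p$v_block && t >= state$refractory_until
  if (fired) {
    state$spike_times <- c(state$spike_times, t)
    state$v_ahp <- state$v_ahp + p$delta_v_ahp
    state$v_thresh <- state$v_thresh + p$w_rel_refrac * (p$v_block - state$v_thresh)
    state$refractory_until <- t + p$tau_abs_refrac
    state$v_syn[] <- 0
  }
  list(state = state, fired = fired)
}
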