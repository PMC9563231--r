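# Glue between R network objects and the C++ event-driven engine.

# Default weight of the external AMPA stimulation event delivered to each
# selected sensory neuron at window start. Must exceed v_thresh - v_rest
# (25 mV for E cells) even under accumulated after-hyperpolarization, while
# keeping the resulting membrane voltage below the depolarization-block
# voltage, so each activated ES neuron fires exactly once per window.
DEFAULT_STIM_WEIGHT <- 35

#' Create a simulation session for a network
#'
#' A session is a mutable engine instance holding the neuron states, the
#' synaptic event queue, the current plastic weights, eligibility tags and
#' homeostasis totals. Sessions are cheap to build; frozen evaluations
#' construct a fresh one so the `snn_network` object is never mutated.
#'
#' @param net An `snn_network`.
#' @param genome Optional genome overriding the network's plastic weights.
#' @return An external pointer of class `snn_session`.
#' @export
make_session <- function(net, genome = NULL) {
  ct_codes <- c(E = 1L, I = 2L, IL = 3L)
  cell_type <- integer(sum(net$populations$size))
  for (i in seq_len(nrow(net$populations))) {
    rng <- seq.int(net$populations$start[i], net$populations$end[i])
    cell_type[rng] <- ct_codes[[net$populations$cell_type[i]]]
  }
  syn <- net$synapses
  sp <- sess_new(
    list(pre = as.integer(syn$pre), post = as.integer(syn$post),
         chan = as.integer(channel_code(syn$channel)),
         weight = as.numeric(syn$weight), delay = as.numeric(syn$delay),
         plastic = as.logical(syn$plastic)),
    cell_param_matrix(), cell_type, chan_param_matrix())
  if (!is.null(genome)) sess_set_weights(sp, genome)
  class(sp) <- c("snn_session", class(sp))
  sp
}

#' Sensory stimulation burst
#'
#' Offsets (ms, within the 50 ms agent step) of the external stimulation
#' events delivered to each activated sensory neuron. The default two-event
#' burst (0 and 15 ms) is the excitability calibration that places the
#' association and motor layers in the 2-20 Hz operating band, near the
#' homeostatic rate set points (5.5 Hz EA, 6.0 Hz EM): with a single event
#' per step, the four activated sensory spikes cannot depolarize downstream
#' neurons to threshold under the published weights and in-degrees, leaving
#' the motor layer silent and the agent inert.
#'
#' @return Numeric vector of event offsets in ms.
#' @export
stimulation_burst <- function() c(0, 15)

# Motor subpopulation ids (fixed by the default layout).
EM_L_IDS <- 141:160
EM_R_IDS <- 161:180
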