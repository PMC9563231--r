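#' Low-level engine interface
#'
#' Direct bindings to the event-driven simulation engine behind
#' [make_session()]. Most analyses should use the high-level functions
#' ([evaluate_frozen()], [run_stdp_training()], [run_evol()],
#' [all_inputs_sweep()]); these primitives are exposed for custom
#' simulation loops and for verification against the pure-R neuron model.
#'
#' * `sess_run_window(sp, stim, stim_weight, window)` simulates one agent
#'   step: injects one external AMPA event per stimulated neuron at window
#'   start, processes the event queue for `window` ms, and returns
#'   per-neuron spike counts. Pending delayed events persist across windows.
#' * `sess_run_episode()` runs a full frozen-weights cart-pole episode
#'   (encode, simulate, decode, step) inside the engine.
#' * `sess_apply_critic()`, `sess_balance_inputs()`,
#'   `sess_scale_reception_targets()` implement the plasticity and
#'   homeostasis updates on the live session.
#' * `sess_state()` returns the lazily-decayed neuron states at the current
#'   session time; `sess_tag_expiry()` the per-genome-position eligibility
#'   expiries; `sess_transmission_totals()` the output-balancing totals.
#' * `neuron_trajectory_event()` and `neuron_trajectory_clock()` simulate a
#'   single neuron through an event sequence with, respectively, the
#'   event-driven lazy-decay updates and a dense clock-driven integration —
#'   two independent code paths used to verify the neuron model.
#'
#' @name engine
#' @keywords internal
#' @aliases sess_new sess_reset sess_clear_eligibility sess_set_tagging
#'   sess_get_weights sess_set_weights sess_run_window sess_time sess_state
#'   sess_tag_expiry sess_apply_critic sess_balance_inputs
#'   sess_scale_reception_targets sess_reception_targets
#'   sess_transmission_totals sess_run_episode sess_sweep cartpole_step_cpp
#'   neuron_trajectory_event neuron_trajectory_clock
#' @export sess_new sess_reset sess_clear_eligibility sess_set_tagging
#' @export sess_get_weights sess_set_weights sess_run_window sess_time
#' @export sess_state sess_tag_expiry sess_apply_critic sess_balance_inputs
#' @export sess_scale_reception_targets sess_reception_targets
#' @export sess_transmission_totals sess_run_episode sess_sweep
#' @export cartpole_step_cpp neuron_trajectory_event neuron_trajectory_clock
NULL
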