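#' STDP-RL parameters
#'
#' Reward-modulated spike-timing-dependent plasticity: a causal
#' pre-before-post spike pair within `windhebb` ms tags the synapse with an
#' eligibility trace that stays live for `lenhebb` ms; a later critic
#' delivery changes every tagged synaptic weight by a constant magnitude
#' `hebbwt * |critic|` (scaled by delivery targeting and output balancing),
#' potentiating for reward and depressing for punishment.
#'
#' Delivery targeting (`targeted_mode`):
#' \describe{
#'   \item{`non_targeted`}{all tagged motor-pathway synapses receive the
#'     critic equally;}
#'   \item{`targeted_main`}{only `EA -> EM` synapses onto the motor
#'     subpopulation that generated the action receive it;}
#'   \item{`targeted_both`}{additionally, the opposite subpopulation
#'     receives sign-flipped reinforcement attenuated by
#'     `opp_em_attenuation`.}
#' }
#' `ES -> EA` synapses (one synapse upstream of the motor decision) receive
#' the critic attenuated by `non_motor_attenuation` when `non_motor_rl` is
#' set, in every mode.
#'
#' The tuned values used in the published runs are not available; these
#' defaults are package defaults, all exposed in the training
#' configuration.
#'
#' @param windhebb Max post-minus-pre interval for tagging (ms).
#' @param lenhebb Eligibility lifetime (ms).
#' @param hebbwt Base weight increment per critic delivery.
#' @param targeted_mode One of `"non_targeted"`, `"targeted_main"`,
#'   `"targeted_both"`.
#' @param opp_em_attenuation Attenuation in `[0, 1]` for opposite-side
#'   delivery under `targeted_both`.
#' @param non_motor_rl Deliver (attenuated) critic to `ES -> EA` synapses.
#' @param non_motor_attenuation Attenuation in `[0, 1]` for `ES -> EA`.
#' @return An `rl_params` list.
#' @export
rl_params <- function(windhebb = 20, lenhebb = 1000, hebbwt = 0.01,
                      targeted_mode = c("targeted_both", "targeted_main", "non_targeted"),
                      opp_em_attenuation = 0.5,
                      non_motor_rl = TRUE, non_motor_attenuation = 0.5) {
  targeted_mode <- match.arg(targeted_mode)
  stopifnot(windhebb > 0, lenhebb > 0, hebbwt > 0,
            opp_em_attenuation >= 0, opp_em_attenuation <= 1,
            non_motor_attenuation >= 0, non_motor_attenuation <= 1)
  structure(list(windhebb = windhebb, lenhebb = lenhebb, hebbwt = hebbwt,
                 targeted_mode = targeted_mode,
                 opp_em_attenuation = opp_em_attenuation,
                 non_motor_rl = non_motor_rl,
                 non_motor_attenuation = non_motor_attenuation),
            class = "rl_params")
}

#' Tag a synapse from a causal spike pair
#'
#' A tag is created iff the postsynaptic spike follows the presynaptic one
#' within the causal window: `0 < post_t - pre_t <= windhebb` (closed upper
#' boundary). Re-tagging a live tag refreshes its expiry rather than
#' stacking (updates have constant magnitude, so stacking would be
#' equivalent).
#'
#' @param pre_t,post_t Pre- and postsynaptic spike times (ms).
#' @param p An [rl_params()] list.
#' @return A list `(tagged_at, expires_at)` or `NULL` when no tag forms.
#' @export
#' @examples
#' on_spike_pair(100, 105, rl_params())   # tagged, expires at 1105
#' on_spike_pair(105, 100, rl_params())   # NULL: acausal
on_spike_pair <- function(pre_t, post_t, p = rl_params()) {
  dt <- post_t - pre_t
  if (dt > 0 && dt <= p$windhebb)
    list(tagged_at = post_t, expires_at = post_t + p$lenhebb)
  else NULL
}

#' Per-synapse delivery scaling for a critic event
#'
#' Computes the scaling `s` applied on top of the critic for every genome
#' position, implementing the targeted-delivery variants (see
#' [rl_params()]).
#'
#' @param net An `snn_network`.
#' @param action The action that was generated: `"left"` or `"right"`.
#' @param p An [rl_params()] list.
#' @return Numeric vector over genome positions.
#' @export
delivery_scaling <- function(net, action = c("left", "right"), p = rl_params()) {
  action <- match.arg(action)
  s <- numeric(length(net$plastic_idx))
  es <- net$plastic_pathway == "ES_EA"
  em <- net$plastic_pathway == "EA_EM"
  onto_left <- em & net$plastic_post %in% EM_L_IDS
  onto_right <- em & net$plastic_post %in% EM_R_IDS
  acting <- if (action == "left") onto_left else onto_right
  opposite <- if (action == "left") onto_right else onto_left
  s[es] <- if (p$non_motor_rl) p$non_motor_attenuation else 0
  switch(p$targeted_mode,
    non_targeted = { s[em] <- 1 },
    targeted_main = { s[acting] <- 1 },
    targeted_both = { s[acting] <- 1; s[opposite] <- -p$opp_em_attenuation }
  )
  s
}

#' Apply a critic delivery to tagged synapses (reference implementation)
#'
#' Pure-R mirror of the engine's update rule: every synapse with a live tag
#' (`tag_expiry >= now`) changes by `hebbwt * critic * s * b`, where `b` is
#' the output-balance factor of its presynaptic neuron (from transmission
#' totals frozen at delivery time), and weights are floored at 0.
#'
#' @param net An `snn_network` (weights at its current genome).
#' @param tag_expiry Numeric vector over genome positions: tag expiry times
#'   (`-Inf` for untagged); see [on_spike_pair()].
#' @param critic Scalar critic value in `[-1, 1]`.
#' @param action Action that generated the step (targeted delivery).
#' @param now Delivery time (ms).
#' @param p An [rl_params()] list.
#' @param homeo A [homeostasis_params()] list (balance clamps); pass
#'   `NULL` to skip output balancing (b = 1).
#' @return The network with updated plastic weights.
#' @export
apply_critic <- function(net, tag_expiry, critic, action, now,
                         p = rl_params(), homeo = homeostasis_params()) {
  if (abs(critic) > 1) stop("critic outside [-1, 1]")
  genome <- extract_genome(net)
  s <- delivery_scaling(net, action, p)
  delta <- p$hebbwt * critic * s
  delta[tag_expiry < now] <- 0
  if (!is.null(homeo)) {
    cur <- rowsum_by(genome, net$plastic_pre, length(net$initial_transmission_totals))
    init <- net$initial_transmission_totals
    b <- rep(1, length(genome))
    pre <- net$plastic_pre
    pos <- delta > 0
    neg <- delta < 0
    b[pos] <- output_balance_factor(init[pre[pos]], cur[pre[pos]], "reward", homeo)
    b[neg] <- output_balance_factor(init[pre[neg]], cur[pre[neg]], "punishment", homeo)
    delta <- delta * b
  }
  set_genome(net, pmax(0, genome + delta))
}

# sum x grouped by integer index, returning a dense vector of length n
rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Discard all eligibility tags
#'
#' Episode-boundary hygiene: tags never carry credit across independent
#' episode initializations.
#'
#' @param net An `snn_network`.
#' @return A fresh tag-expiry vector (all `-Inf`) over genome positions.
#' @export
clear_tags <- function(net) {
  rep(-Inf, length(net$plastic_idx))
}

#' Train a network with STDP-RL
#'
#' The 50 ms synchronization loop: at each agent step the game state is
#' encoded into four sensory activations, the network is simulated for one
#' window, the motor spike counts decode the action, the environment
#' advances, the critic scores the transition, and the critic is delivered
#' to all live eligibility tags with targeted scaling and output balancing.
#' Input balancing runs every `input_balance_interval` agent steps and
#' homeostatic gain control every `homeo_interval` steps (rates measured
#' over the trailing `rate_window` steps). Tags are cleared and the neural
#' state reset at every episode boundary.
#'
#' Training can be split into phases with different plasticity/critic
#' settings via `phases`; by default a single phase of `duration_s`
#' simulated seconds is run.
#'
#' @param net An `snn_network` with plastic synapses registered.
#' @param duration_s Simulated seconds to train (ignored when `phases`
#'   given); one agent step is 50 ms, so 500 s = 10,000 steps.
#' @param phases Optional list of `list(duration_s, rl, critic)` phase
#'   entries.
#' @param rl,critic,homeo Parameter lists.
#' @param rf,env,stim_weight Simulation configuration.
#' @param seed Master seed (episode starts, tie-breaks).
#' @param verbose Print per-episode progress.
#' @return An `stdp_fit` list: trained `network`, `episodes` log tibble
#'   (episode, steps), total `steps`, final `reception_targets`.
#' @export
run_stdp_training <- function(net, duration_s = 500, phases = NULL,
                              rl = rl_params(), critic = critic_params(),
                              homeo = homeostasis_params(),
                              rf = build_receptive_fields(),
                              env = cartpole_params(), seed = 1,
                              stim_weight = DEFAULT_STIM_WEIGHT,
                              stim_offsets = stimulation_burst(),
                              verbose = FALSE) {
  if (is.null(phases))
    phases <- list(list(duration_s = duration_s, rl = rl, critic = critic))
  sp <- make_session(net)
  window <- 50
  n_pop <- sum(net$populations$size)
  ea_ids <- population_ids(net$populations, "EA")
  em_ids <- c(EM_L_IDS, EM_R_IDS)
  ea_buf <- integer(homeo$rate_window)
  em_buf <- integer(homeo$rate_window)
  global_step <- 0L
  episode <- 0L
  ep_log <- list()
  with_seed(substream_seed(seed, "stdp-ties"), {
    for (ph in phases) {
      p_rl <- ph$rl %||% rl
      p_cr <- ph$critic %||% critic
      sess_set_tagging(sp, TRUE, p_rl$windhebb, p_rl$lenhebb)
      s_left <- delivery_scaling(net, "left", p_rl)
      s_right <- delivery_scaling(net, "right", p_rl)
      steps_left <- as.integer(round(ph$duration_s / (window / 1000)))
      while (steps_left > 0L) {
        episode <- episode + 1L
        st <- cartpole_reset(substream_seed(seed, "stdp-episodes", episode))
        sess_reset(sp)
        sess_clear_eligibility(sp)
        ep_steps <- 0L
        repeat {
          ids <- encode_state(st, rf)
          counts <- sess_run_window(sp, ids, stim_weight, window, stim_offsets)
          nl <- sum(counts[EM_L_IDS]); nr <- sum(counts[EM_R_IDS])
          no_move <- nl == nr
          action <- if (nl > nr) "left"
          else if (nr > nl) "right"
          else if (runif(1) < 0.5) "left" else "right"
          out <- cartpole_step(st, action, env)
          cv <- compute_critic(st, out$state, no_move, p_cr)
          if (cv != 0) {
            s <- if (action == "left") s_left else s_right
            sess_apply_critic(sp, s, cv, p_rl$hebbwt, sess_time(sp), TRUE,
                              homeo$out_balance_min, homeo$out_balance_max)
          }
          st <- out$state
          global_step <- global_step + 1L
          steps_left <- steps_left - 1L
          ep_steps <- ep_steps + 1L
          slot <- (global_step - 1L) %% homeo$rate_window + 1L
          ea_buf[slot] <- sum(counts[ea_ids])
          em_buf[slot] <- sum(counts[em_ids])
          if (global_step %% homeo$input_balance_interval == 0L)
            sess_balance_inputs(sp)
          if (global_step %% homeo$homeo_interval == 0L) {
            nw <- min(global_step, homeo$rate_window)
            rate_ea <- sum(ea_buf) / (length(ea_ids) * nw * window / 1000)
            rate_em <- sum(em_buf) / (length(em_ids) * nw * window / 1000)
            f <- rep(1, n_pop)
            f[ea_ids] <- homeo_factor(rate_ea, homeo$target_rate_ea, homeo$homeo_scale)
            f[em_ids] <- homeo_factor(rate_em, homeo$target_rate_em, homeo$homeo_scale)
            sess_scale_reception_targets(sp, f)
          }
          if (out$terminated || ep_steps >= env$max_steps || steps_left <= 0L) break
        }
        ep_log[[episode]] <- c(episode = episode, steps = ep_steps)
        if (verbose && episode %% 50 == 0)
          message(sprintf("episode %d: %d steps (%d agent steps left)",
                          episode, ep_steps, steps_left))
      }
    }
  })
  log <- tibble::as_tibble(do.call(rbind, ep_log))
  structure(list(
    network = set_genome(net, sess_get_weights(sp)),
    episodes = structure(log, class = c("stdp_log", class(log))),
    steps = global_step,
    reception_targets = sess_reception_targets(sp)
  ), class = "stdp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trailing moving average
#'
#' @param x Numeric vector.
#' @param width Window width (default 100, the episode-averaging window
#'   used to quantify training performance).
#' @return Vector of trailing means (shorter head windows averaged as-is).
#' @export
moving_average <- function(x, width = 100) {
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(0, seq_len(n) - width)
  (cs - c(0, cs)[lo + 1]) / (seq_len(n) - lo)
}
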