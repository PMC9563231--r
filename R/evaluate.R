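#' Fixed episode datasets for model selection and reporting
#'
#' Two disjoint sets of 100 fixed episode start states, derived from
#' independent substreams of one master seed: a validation set (used to
#' pick a model time-point during training) and a testing set (used to
#' report final performance). All four state variables of every episode are
#' drawn Uniform(-0.05, 0.05).
#'
#' @param master_seed Integer master seed.
#' @param n Episodes per dataset (default 100).
#' @return A list with `validation` and `testing`, each an `n x 4` matrix.
#' @export
episode_datasets <- function(master_seed, n = 100) {
  draw <- function(name) {
    with_seed(substream_seed(master_seed, name),
              matrix(runif(4 * n, -0.05, 0.05), ncol = 4,
                     dimnames = list(NULL, c("position", "velocity", "angle",
                                             "angular_velocity"))))
  }
  list(validation = draw("validation-episodes"), testing = draw("testing-episodes"))
}

#' Evaluate a network with frozen weights on fixed episodes
#'
#' Runs each episode with all plasticity and normalization disabled: the
#' state is encoded into four sensory activations, the network is simulated
#' for one 50 ms window per step, the motor spike counts decode the action
#' (ties broken by a seeded stream), and the environment advances until
#' failure or the 500-step cap.
#'
#' @param net An `snn_network`.
#' @param episodes Matrix of start states (rows = episodes, 4 columns),
#'   e.g. one element of [episode_datasets()].
#' @param rf Receptive fields from [build_receptive_fields()].
#' @param env Environment constants from [cartpole_params()].
#' @param genome Optional genome to evaluate instead of the network's
#'   current plastic weights.
#' @param tie_seed Seed for the winner-take-all tie-break stream.
#' @param stim_weight External stimulation weight.
#' @return A `frozen_eval` list: per-episode `steps`, `mean`, `median`.
#' @export
#' @examples
#' \donttest{
#' net <- build_network(6)
#' ds <- episode_datasets(1, n = 5)
#' evaluate_frozen(net, ds$testing)$mean
#' }
evaluate_frozen <- function(net, episodes, rf = build_receptive_fields(),
                            env = cartpole_params(), genome = NULL,
                            tie_seed = 1, stim_weight = DEFAULT_STIM_WEIGHT,
                            stim_offsets = stimulation_burst()) {
  sp <- make_session(net, genome)
  steps <- vapply(seq_len(nrow(episodes)), function(i) {
    out <- sess_run_episode(sp, as.numeric(episodes[i, ]), rf$boundaries, env,
                            env$max_steps, 50, stim_weight,
                            substream_seed(tie_seed, "tie-break", i), FALSE,
                            stim_offsets)
    out$steps
  }, numeric(1))
  structure(list(steps = steps, mean = mean(steps), median = median(steps)),
            class = "frozen_eval")
}

#' @export
print.frozen_eval <- function(x, ...) {
  cat("<frozen_eval>", length(x$steps), "episodes; mean",
      round(x$mean, 2), "median", x$median, "steps/episode\n")
  invisible(x)
}

#' Run a single frozen-weights episode
#'
#' @inheritParams evaluate_frozen
#' @param start Numeric start state (length 4).
#' @param record Return per-step actions, motor counts and states.
#' @return A list with `steps` and, when `record = TRUE`, `actions`
#'   (0 = left, 1 = right), `n_left`, `n_right` and a 4 x steps `states`
#'   matrix.
#' @export
run_episode <- function(net, start, rf = build_receptive_fields(),
                        env = cartpole_params(), genome = NULL, tie_seed = 1,
                        stim_weight = DEFAULT_STIM_WEIGHT, record = FALSE,
                        stim_offsets = stimulation_burst()) {
  sp <- make_session(net, genome)
  sess_run_episode(sp, as.numeric(start), rf$boundaries, env, env$max_steps,
                   50, stim_weight, tie_seed, record, stim_offsets)
}

#' Assemble a performance comparison report
#'
#' Binds named frozen evaluations into one tidy table (model, mean, median,
#' episodes) — the end-to-end structure used to compare initialization,
#' STDP-RL and evolutionary training for each wiring seed.
#'
#' @param ... Named `frozen_eval` objects.
#' @return A tibble with one row per model.
#' @export
performance_report <- function(...) {
  evs <- list(...)
  tibble::tibble(
    model = names(evs),
    mean_steps = unname(vapply(evs, function(e) e$mean, numeric(1))),
    median_steps = unname(vapply(evs, function(e) e$median, numeric(1))),
    n_episodes = unname(vapply(evs, function(e) length(e$steps), numeric(1)))
  )
}
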