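#' Evolutionary-strategy parameters
#'
#' Population-level, gradient-free training over the plastic-weight genome.
#' Each iteration samples `population` standard-normal perturbation rows,
#' evaluates every multiplicatively perturbed genome on
#' `episodes_per_eval` fresh episodes, normalizes the fitness vector, and
#' moves the genome along the fitness-weighted perturbation average.
#'
#' @param population Number of perturbations per iteration (P, default 10).
#' @param sigma Perturbation scale (default 0.1).
#' @param alpha Learning rate (default 1.0).
#' @param episodes_per_eval Episodes averaged per fitness evaluation (X,
#'   default 5).
#' @param iterations Iteration budget (default 1500; 1600 reproduces the
#'   longer published runs).
#' @return An `evol_params` list.
#' @export
evol_params <- function(population = 10, sigma = 0.1, alpha = 1.0,
                        episodes_per_eval = 5, iterations = 1500) {
  stopifnot(population >= 2, sigma > 0, episodes_per_eval >= 1)
  structure(list(population = as.integer(population), sigma = sigma,
                 alpha = alpha, episodes_per_eval = as.integer(episodes_per_eval),
                 iterations = as.integer(iterations)), class = "evol_params")
}

#' Multiplicatively perturb a genome
#'
#' `w * (1 + sigma * eps)`, floored at 0: multiplicative noise keeps the
#' search relative to each weight's scale and (with the floor) restricts
#' the genome to valid non-negative synaptic weights.
#'
#' @param w Genome vector.
#' @param eps Standard-normal perturbation vector, same length.
#' @param sigma Perturbation scale.
#' @return Perturbed genome (non-negative).
#' @export
perturb_genome <- function(w, eps, sigma) {
  if (length(w) != length(eps)) stop("length mismatch")
  pmax(0, w * (1 + sigma * eps))
}

#' Normalize a fitness vector
#'
#' Centers by the population mean and scales by the population (1/P)
#' standard deviation. A zero-variance fitness vector returns all zeros,
#' which makes the subsequent update a no-op.
#'
#' @param f Numeric fitness vector (length >= 2).
#' @return Normalized fitness vector.
#' @export
#' @examples
#' normalize_fitness(c(10, 20))   # -1, +1
normalize_fitness <- function(f) {
  if (length(f) < 2) stop("need at least 2 fitness values")
  s <- sqrt(mean((f - mean(f))^2))
  if (s == 0) return(rep(0, length(f)))
  (f - mean(f)) / s
}

#' Evolutionary genome update
#'
#' Per synapse k: `w_k <- w_k * (1 + alpha * sigma * sum_j(eps[j,k] * N[j]) / P)`,
#' floored at 0.
#'
#' @param w Genome vector.
#' @param eps `P x n` perturbation matrix (rows as sampled).
#' @param n_fit Normalized fitness vector of length P.
#' @param p An [evol_params()] list.
#' @return Updated genome.
#' @export
update_genome <- function(w, eps, n_fit, p) {
  if (!is.matrix(eps) || nrow(eps) != length(n_fit) || ncol(eps) != length(w))
    stop("shape mismatch")
  pmax(0, w * (1 + p$alpha * p$sigma * as.numeric(crossprod(eps, n_fit)) / nrow(eps)))
}

#' Episodic fitness of a genome
#'
#' Mean steps survived over `X` episodes with the genome's weights frozen
#' (no plasticity, no normalization). Fitness lies in `[1, 500]`.
#'
#' @param net An `snn_network`.
#' @param genome Plastic-weight genome to evaluate.
#' @param starts `X x 4` matrix of episode start states.
#' @param rf,env,stim_weight Simulation configuration.
#' @param tie_seed Seed for the tie-break stream.
#' @return Mean steps survived.
#' @export
evaluate_fitness <- function(net, genome, starts, rf = build_receptive_fields(),
                             env = cartpole_params(), tie_seed = 1,
                             stim_weight = DEFAULT_STIM_WEIGHT) {
  evaluate_frozen(net, starts, rf, env, genome, tie_seed, stim_weight)$mean
}

#' Train a network with the evolutionary strategy
#'
#' Runs the full loop: sample perturbations, evaluate each perturbed genome
#' on fresh random episodes (episode start states are drawn from a
#' per-(iteration, perturbation) substream, so evaluation order is
#' irrelevant), normalize fitness, update the genome. Weights stay
#' non-negative throughout; synaptic plasticity and homeostatic
#' normalization are fully inactive.
#'
#' @param net An `snn_network`.
#' @param p An [evol_params()] list.
#' @param seed Master seed for perturbation noise, episode starts and
#'   tie-breaks.
#' @param rf,env,stim_weight Simulation configuration.
#' @param target_fitness Optional early-stop threshold on an iteration's
#'   mean fitness (mean over the P * X episodes).
#' @param fitness_fn Optional replacement fitness `function(genome, iter, j)`
#'   (used for surrogate-landscape testing).
#' @param verbose Print per-iteration progress.
#' @return An `evol_fit` list: final `genome`, `log` tibble (iteration,
#'   min/mean/max fitness), the trained `network`, and `params`.
#' @export
run_evol <- function(net, p = evol_params(), seed = 1,
                     rf = build_receptive_fields(), env = cartpole_params(),
                     stim_weight = DEFAULT_STIM_WEIGHT, target_fitness = NULL,
                     fitness_fn = NULL, verbose = FALSE,
                     stim_offsets = stimulation_burst()) {
  w <- extract_genome(net)
  n <- length(w)
  sp <- if (is.null(fitness_fn)) make_session(net) else NULL
  logs <- vector("list", p$iterations)
  iters_run <- 0L
  for (it in seq_len(p$iterations)) {
    eps <- with_seed(substream_seed(seed, "evol-noise", it),
                     matrix(rnorm(p$population * n), nrow = p$population))
    fit <- numeric(p$population)
    for (j in seq_len(p$population)) {
      wj <- perturb_genome(w, eps[j, ], p$sigma)
      if (is.null(fitness_fn)) {
        sess_set_weights(sp, wj)
        starts <- with_seed(substream_seed(seed, "evol-episodes", it * 1000L + j),
                            matrix(runif(4 * p$episodes_per_eval, -0.05, 0.05), ncol = 4))
        steps <- vapply(seq_len(p$episodes_per_eval), function(e) {
          sess_run_episode(sp, starts[e, ], rf$boundaries, env, env$max_steps,
                           50, stim_weight,
                           substream_seed(seed, "evol-tie", (it * 1000L + j) * 100L + e),
                           FALSE, stim_offsets)$steps
        }, numeric(1))
        fit[j] <- mean(steps)
      } else {
        fit[j] <- fitness_fn(wj, it, j)
      }
    }
    w <- update_genome(w, eps, normalize_fitness(fit), p)
    logs[[it]] <- c(iteration = it, min = min(fit), mean = mean(fit), max = max(fit))
    iters_run <- it
    if (verbose) message(sprintf("iter %d: fitness min %.1f mean %.1f max %.1f",
                                 it, min(fit), mean(fit), max(fit)))
    if (!is.null(target_fitness) && mean(fit) >= target_fitness) break
  }
  log <- tibble::as_tibble(do.call(rbind, logs[seq_len(iters_run)]))
  structure(list(genome = w, log = structure(log, class = c("evol_log", class(log))),
                 network = set_genome(net, w), params = p, seed = seed),
            class = "evol_fit")
}
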