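#' Build the sensory receptive-field map
#'
#' Each of the four state variables is encoded by one 20-neuron sensory
#' group using a population place code: the real line is partitioned into
#' the 20 equal-probability slices of a zero-mean Gaussian, giving narrow
#' receptive fields near the balanced state (value 0) and broad fields at
#' the periphery. The 19 interior boundaries sit at
#' \eqn{\Phi^{-1}(k/20)\,\sigma}, k = 1..19. Neurons 1-10 of a group cover
#' negative values (neuron 1 most negative), neurons 11-20 positive values
#' in increasing order; a value of exactly 0 maps to neuron 11.
#'
#' @param sigma Named or positional numeric vector of 4 positive standard
#'   deviations for (position, velocity, angle, angular velocity). The
#'   defaults are calibrated so that random-policy rollouts occupy most
#'   bins; [estimate_sigmas()] recomputes them empirically.
#' @return A `receptive_fields` object holding `sigma` and a 19 x 4
#'   `boundaries` matrix.
#' @export
#' @examples
#' rf <- build_receptive_fields()
#' rf$boundaries[10, ]   # the 0 boundary between neurons 10 and 11
build_receptive_fields <- function(sigma = c(position = 0.5, velocity = 0.5,
                                             angle = 0.05, angular_velocity = 0.4)) {
  if (length(sigma) != 4 || any(sigma <= 0)) stop("sigma must be 4 positive values")
  b <- outer(qnorm((1:19) / 20), as.numeric(sigma))
  colnames(b) <- c("position", "velocity", "angle", "angular_velocity")
  structure(list(sigma = sigma, boundaries = b), class = "receptive_fields")
}

#' Encode a game state as four sensory neuron ids
#'
#' Selects exactly one neuron per 20-neuron sensory group: the neuron whose
#' receptive-field bin contains the variable's value (values beyond the
#' extreme boundaries clamp to neurons 1 or 20). These four neurons each
#' receive one suprathreshold external AMPA event at the start of the 50 ms
#' agent step — the only external input to the network.
#'
#' @param state Numeric state vector (position, velocity, angle, angular
#'   velocity).
#' @param rf A [build_receptive_fields()] map.
#' @return Integer vector of 4 global ES neuron ids (in 1..80, one per group).
#' @export
#' @examples
#' encode_state(c(0, 0, 0, 0), build_receptive_fields())   # 11 31 51 71
encode_state <- function(state, rf) {
  vapply(1:4, function(v) {
    bin <- findInterval(state[[v]], rf$boundaries[, v]) + 1L
    (v - 1L) * 20L + bin
  }, integer(1))
}

#' Decode a motor action from spike counts
#'
#' Winner-take-all over the two motor subpopulations: the side with the
#' strict spike-count majority in the 50 ms window wins; a tie (including
#' 0-0) sets the `no_move` flag and draws the action uniformly from the
#' current R RNG.
#'
#' @param n_left,n_right Spike counts of `EM_L` and `EM_R` in the window.
#' @return A list with `action` (`"left"`/`"right"`), `n_left`, `n_right`
#'   and `no_move`.
#' @export
decode_action <- function(n_left, n_right) {
  no_move <- n_left == n_right
  action <- if (n_left > n_right) "left"
  else if (n_right > n_left) "right"
  else if (runif(1) < 0.5) "left" else "right"
  list(action = action, n_left = n_left, n_right = n_right, no_move = no_move)
}

#' Estimate encoder sigmas from random-policy rollouts
#'
#' Plays `n_episodes` random-policy episodes and returns the per-variable
#' standard deviation of the visited states — an empirical choice for the
#' receptive-field widths matching each input's observed spread.
#'
#' @param n_episodes Number of episodes to sample.
#' @param params Environment constants.
#' @param seed RNG seed.
#' @return Named numeric vector of 4 standard deviations.
#' @export
estimate_sigmas <- function(n_episodes = 50, params = cartpole_params(), seed = 1) {
  states <- with_seed(substream_seed(seed, "sigma-estimate"), {
    out <- list()
    for (e in seq_len(n_episodes)) {
      st <- runif(4, -0.05, 0.05)
      repeat {
        out[[length(out) + 1]] <- st
        act <- if (runif(1) < 0.5) "left" else "right"
        step <- cartpole_step(st, act, params)
        st <- step$state
        if (step$terminated || length(out) > 1e5) break
      }
    }
    do.call(rbind, out)
  })
  stats::setNames(apply(states, 2, sd),
                  c("position", "velocity", "angle", "angular_velocity"))
}
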