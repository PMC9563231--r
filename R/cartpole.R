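#' Cart-pole environment parameters
#'
#' Constants of the classic cart-pole control task as published in the
#' CartPole-v1 definition: a 1.0 kg cart with a 0.1 kg pole of half-length
#' 0.5, a fixed +/-10 N force, explicit Euler integration at dt = 0.02 s,
#' and termination when |position| > 2.4 or |angle| exceeds the angle limit
#' (12 degrees by default; a 15-degree variant is supported via
#' `angle_limit_deg`). Episodes are capped at 500 steps.
#'
#' @param angle_limit_deg Failure angle in degrees (default 12).
#' @param max_steps Episode cap (default 500).
#' @return A named list of environment constants (`angle_limit` in radians).
#' @export
cartpole_params <- function(angle_limit_deg = 12, max_steps = 500) {
  list(
    gravity = 9.8, mass_cart = 1.0, mass_pole = 0.1, half_length = 0.5,
    force_mag = 10.0, dt = 0.02,
    angle_limit = angle_limit_deg * pi / 180,
    position_limit = 2.4,
    max_steps = as.integer(max_steps)
  )
}

#' Reset the cart-pole to a random start state
#'
#' All four state variables (position, velocity, angle, angular velocity)
#' are drawn Uniform(-0.05, 0.05), the CartPole-v1 convention. Uses the
#' current R RNG unless `episode_seed` is given.
#'
#' @param episode_seed Optional integer; when given, the draw is made from a
#'   private stream and the caller's RNG state is untouched.
#' @return Named numeric vector `(position, velocity, angle, angular_velocity)`.
#' @export
cartpole_reset <- function(episode_seed = NULL) {
  draw <- function() runif(4, -0.05, 0.05)
  x <- if (is.null(episode_seed)) draw() else with_seed(episode_seed, draw())
  names(x) <- c("position", "velocity", "angle", "angular_velocity")
  x
}

#' Advance the cart-pole one step
#'
#' One explicit-Euler integration step of the standard cart-pole dynamics.
#' With the pole angle \eqn{\theta}, pole mass \eqn{m}, cart mass \eqn{M},
#' half-length \eqn{l} and applied force \eqn{F}:
#' \deqn{\ddot\theta = \frac{g\sin\theta - \cos\theta\,
#'   \frac{F + m l \dot\theta^2 \sin\theta}{M+m}}
#'   {l\left(\frac{4}{3} - \frac{m\cos^2\theta}{M+m}\right)}, \qquad
#'   \ddot x = \frac{F + m l \dot\theta^2 \sin\theta}{M+m}
#'             - \frac{m l \ddot\theta \cos\theta}{M+m}.}
#'
#' @param state Named numeric state vector (see [cartpole_reset()]).
#' @param action `"left"` or `"right"`.
#' @param params Environment constants from [cartpole_params()].
#' @return A list with the successor `state` and a `terminated` flag.
#' @export
#' @examples
#' cartpole_step(cartpole_reset(1), "right")
cartpole_step <- function(state, action = c("left", "right"), params = cartpole_params()) {
  action <- match.arg(action)
  if (is_terminal(state, params)) stop("cannot step a terminated state")
  force <- if (action == "right") params$force_mag else -params$force_mag
  total_mass <- params$mass_cart + params$mass_pole
  pml <- params$mass_pole * params$half_length
  ct <- cos(state[[3]]); sn <- sin(state[[3]])
  temp <- (force + pml * state[[4]]^2 * sn) / total_mass
  thetaacc <- (params$gravity * sn - ct * temp) /
    (params$half_length * (4 / 3 - params$mass_pole * ct^2 / total_mass))
  xacc <- temp - pml * thetaacc * ct / total_mass
  new <- c(
    position = state[[1]] + params$dt * state[[2]],
    velocity = state[[2]] + params$dt * xacc,
    angle = state[[3]] + params$dt * state[[4]],
    angular_velocity = state[[4]] + params$dt * thetaacc
  )
  list(state = new, terminated = is_terminal(new, params))
}

is_terminal <- function(state, params = cartpole_params()) {
  abs(state[[1]]) > params$position_limit || abs(state[[3]]) > params$angle_limit
}

#' Run episodes under a uniformly random policy
#'
#' The null model: at every step LEFT or RIGHT is chosen with probability
#' 1/2. Used as the baseline an untrained network is compared against.
#'
#' @param starts Matrix of start states (one row per episode, 4 columns) or
#'   an integer count of random episodes.
#' @param params Environment constants.
#' @param seed Seed for action draws (and resets when `starts` is a count).
#' @return Integer vector of steps survived per episode.
#' @export
random_policy_episodes <- function(starts, params = cartpole_params(), seed = 1) {
  if (length(starts) == 1 && is.numeric(starts)) {
    starts <- with_seed(substream_seed(seed, "random-policy-starts"),
                        matrix(runif(4 * starts, -0.05, 0.05), ncol = 4))
  }
  with_seed(substream_seed(seed, "random-policy-actions"), {
    apply(starts, 1, function(s0) {
      st <- s0
      steps <- 0L
      repeat {
        act <- if (runif(1) < 0.5) "left" else "right"
        out <- cartpole_step(st, act, params)
        st <- out$state
        steps <- steps + 1L
        if (out$terminated || steps >= params$max_steps) break
      }
      steps
    })
  })
}
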