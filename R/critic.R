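#' Critic parameters
#'
#' The hand-crafted critic turns consecutive game states into a scalar
#' reinforcement signal in `[-max_reward, max_reward]`. The per-state loss
#' weighs the squared pole angle against the squared angular velocity
#' (`eta_angvel`); the positivity bias `eta_positivity` (>= 1) boosts
#' rewards relative to punishments, since early training is dominated by
#' punishment; `gain` is a final multiplier before clamping. `max_reward`
#' is fixed at 1. States with loss below `loss_epsilon` count as balanced.
#'
#' The tuned values of `eta_positivity`, `eta_angvel` and `gain` are not
#' published; the defaults here are documented package defaults, exposed in
#' the training configuration.
#'
#' @param eta_angvel Weight on squared angular velocity in the loss.
#' @param eta_positivity Positivity bias (>= 1).
#' @param gain Final multiplier (> 0).
#' @param max_reward Clamp magnitude, fixed at 1.
#' @param loss_epsilon Near-balance threshold (1e-2).
#' @return A `critic_params` list.
#' @export
critic_params <- function(eta_angvel = 0.5, eta_positivity = 2, gain = 5,
                          max_reward = 1.0, loss_epsilon = 1e-2) {
  stopifnot(eta_positivity >= 1, gain > 0, max_reward == 1.0)
  structure(list(eta_angvel = eta_angvel, eta_positivity = eta_positivity,
                 gain = gain, max_reward = max_reward,
                 loss_epsilon = loss_epsilon), class = "critic_params")
}

#' Per-state loss used by the critic
#'
#' `loss = angle^2 + eta_angvel * angular_velocity^2` — an even function of
#' both arguments, zero only at perfect balance.
#'
#' @param state Numeric state vector (position, velocity, angle, angular
#'   velocity).
#' @param p A [critic_params()] list.
#' @return Non-negative scalar.
#' @export
cartpole_loss <- function(state, p = critic_params()) {
  state[[3]]^2 + p$eta_angvel * state[[4]]^2
}

#' Raw reward between two consecutive states
#'
#' The piecewise cases apply in order, first match wins:
#' \enumerate{
#'   \item previous loss below `loss_epsilon` (already balanced): 0;
#'   \item `no_move` (spike-count tie): `-max_reward / eta_positivity`;
#'   \item current loss below `loss_epsilon` (reached balance):
#'     `+max_reward / eta_positivity`;
#'   \item otherwise the loss decrease `loss(prev) - loss(cur)`.
#' }
#'
#' @param prev,cur Previous and current game states.
#' @param no_move Logical: the decoder tied and the move was random.
#' @param p A [critic_params()] list.
#' @return Scalar reward (any sign).
#' @export
cartpole_reward <- function(prev, cur, no_move, p = critic_params()) {
  if (cartpole_loss(prev, p) < p$loss_epsilon) return(0)
  if (no_move) return(-p$max_reward / p$eta_positivity)
  if (cartpole_loss(cur, p) < p$loss_epsilon) return(p$max_reward / p$eta_positivity)
  cartpole_loss(prev, p) - cartpole_loss(cur, p)
}

#' Final critic value
#'
#' Positive rewards are boosted by `eta_positivity`, the result is scaled
#' by `gain` and clamped to `[-max_reward, max_reward]`.
#'
#' @param r Raw reward from [cartpole_reward()].
#' @param p A [critic_params()] list.
#' @return Scalar in `[-1, 1]`.
#' @export
critic_value <- function(r, p = critic_params()) {
  rp <- if (r > 0) r * p$eta_positivity else r
  max(-p$max_reward, min(rp * p$gain, p$max_reward))
}

#' Critic signal for one transition
#'
#' Convenience composition of [cartpole_reward()] and [critic_value()].
#'
#' @inheritParams cartpole_reward
#' @return Scalar critic value in `[-1, 1]`.
#' @export
compute_critic <- function(prev, cur, no_move, p = critic_params()) {
  critic_value(cartpole_reward(prev, cur, no_move, p), p)
}
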