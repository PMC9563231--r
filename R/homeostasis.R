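#' Synaptic homeostasis parameters
#'
#' Three normalization mechanisms keep STDP-RL training from running away:
#' \describe{
#'   \item{input balancing}{every `input_balance_interval` agent steps,
#'     each neuron's summed incoming plastic weight is rescaled to its
#'     reception target (initially the build-time total), creating
#'     synaptic competition;}
#'   \item{output balancing}{every critic delivery is scaled per synapse by
#'     the presynaptic neuron's transmission-total ratio, damping reward to
#'     neurons whose total output has grown and boosting their punishment
#'     (clamped to `[out_balance_min, out_balance_max]`);}
#'   \item{homeostatic gain control}{every `homeo_interval` steps the
#'     reception targets themselves drift by `homeo_scale` (0.01%) up or
#'     down, steering population firing rates (measured over the trailing
#'     `rate_window` steps) toward 5.5 Hz for EA and 6.0 Hz for EM.}
#' }
#' All three run only while STDP-RL is active; they are inert during
#' evolutionary training and frozen-weight evaluation.
#'
#' @param input_balance_interval Agent steps between input balancing.
#' @param homeo_interval Agent steps between gain-control checks.
#' @param rate_window Trailing window (agent steps) for rate estimates.
#' @param target_rate_ea,target_rate_em Population rate set points (Hz).
#' @param homeo_scale Per-check relative target adjustment (1e-4 = 0.01%).
#' @param out_balance_min,out_balance_max Output-balance clamp.
#' @return A `homeostasis_params` list.
#' @export
homeostasis_params <- function(input_balance_interval = 25, homeo_interval = 75,
                               rate_window = 500, target_rate_ea = 5.5,
                               target_rate_em = 6.0, homeo_scale = 1e-4,
                               out_balance_min = 0.1, out_balance_max = 2.0) {
  stopifnot(input_balance_interval > 0, homeo_interval > 0,
            out_balance_min > 0, out_balance_min <= 1, out_balance_max >= 1)
  structure(list(input_balance_interval = as.integer(input_balance_interval),
                 homeo_interval = as.integer(homeo_interval),
                 rate_window = as.integer(rate_window),
                 target_rate_ea = target_rate_ea, target_rate_em = target_rate_em,
                 homeo_scale = homeo_scale,
                 out_balance_min = out_balance_min,
                 out_balance_max = out_balance_max), class = "homeostasis_params")
}

#' Balance each neuron's total plastic input
#'
#' Rescales every postsynaptic neuron's incoming plastic weights by a
#' common factor so their sum equals that neuron's reception target.
#' Neurons whose current total is zero are left unchanged.
#'
#' @param net An `snn_network`.
#' @param targets Per-neuron reception targets; defaults to the build-time
#'   totals (`net$initial_reception_totals`), possibly drifted by
#'   [homeostatic_gain()].
#' @return The network with rebalanced plastic weights.
#' @export
#' @examples
#' # two incoming weights 30 and 90 against a target of 100 become 25, 75
balance_inputs <- function(net, targets = net$initial_reception_totals) {
  genome <- extract_genome(net)
  post <- net$plastic_post
  cur <- rowsum_by(genome, post, length(targets))
  f <- ifelse(cur > 0, targets / ifelse(cur > 0, cur, 1), 1)
  set_genome(net, genome * f[post])
}

#' Output-balance factor for a critic delivery
#'
#' With transmission ratio `rho = initial_total / current_total`, rewards
#' are scaled by `clamp(rho, min, max)` and punishments by
#' `clamp(1 / rho, min, max)`: a synapse whose presynaptic neuron's total
#' output has grown beyond its initial value receives weaker rewards and
#' stronger punishments, and vice versa. A zero current total yields the
#' max factor for rewards and the min for punishments.
#'
#' @param initial_total,current_total Presynaptic plastic transmission
#'   totals (vectorized).
#' @param sign `"reward"` or `"punishment"`.
#' @param p A [homeostasis_params()] list.
#' @return Clamp-bounded factor(s) in `[out_balance_min, out_balance_max]`.
#' @export
output_balance_factor <- function(initial_total, current_total,
                                  sign = c("reward", "punishment"),
                                  p = homeostasis_params()) {
  sign <- match.arg(sign)
  rho <- ifelse(current_total > 0, initial_total / ifelse(current_total > 0, current_total, 1), NA)
  raw <- if (sign == "reward") rho else 1 / rho
  fallback <- if (sign == "reward") p$out_balance_max else p$out_balance_min
  out <- pmin(pmax(raw, p$out_balance_min), p$out_balance_max)
  out[is.na(out)] <- fallback
  out
}

# target multiplier for one homeostatic check
homeo_factor <- function(rate, target, scale) {
  if (rate > target) 1 - scale else if (rate < target) 1 + scale else 1
}

#' Homeostatic gain control of reception targets
#'
#' Nudges each neuron's reception target by `homeo_scale`: down when its
#' population fires above the target rate, up when below, unchanged at the
#' set point. The drifted targets feed the next [balance_inputs()] call;
#' weights are never touched directly.
#'
#' @param targets Per-neuron reception targets.
#' @param observed_rate Observed rate (Hz) per neuron (typically its
#'   population's rate, recycled).
#' @param target_rate Set-point rate (Hz) per neuron.
#' @param p A [homeostasis_params()] list.
#' @return Updated targets.
#' @export
homeostatic_gain <- function(targets, observed_rate, target_rate,
                             p = homeostasis_params()) {
  f <- ifelse(observed_rate > target_rate, 1 - p$homeo_scale,
              ifelse(observed_rate < target_rate, 1 + p$homeo_scale, 1))
  targets * f
}
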