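#' All-inputs sweep of a frozen network
#'
#' Dissects a frozen circuit by enumerating sensory activation quadruples —
#' one neuron per 20-neuron sensory group, 20^4 = 160,000 combinations in
#' lexicographic order (position group most significant) — stimulating each
#' in turn, and recording which neurons spiked in the response window and
#' which action the motor populations decoded. Activations are interleaved
#' with blank periods long enough that no spiking leaks into the next
#' activation; leaked (residual) spikes are counted and reported.
#'
#' @param net An `snn_network` (weights frozen; never mutated).
#' @param stride Enumerate every `stride`-th combination (1 = full sweep).
#' @param window Response window (ms).
#' @param blank Blank period between activations (ms).
#' @param stim_weight External stimulation weight.
#' @param tie_seed Seed for tie-break draws.
#' @param genome Optional genome overriding the network's weights.
#' @return A `sweep_records` list: `records` tibble (combo index, the four
#'   1-based bin indices, activated ES ids, motor counts, decoded `action`,
#'   `tie` flag, residual spike count) and `active`, a records x neurons
#'   logical matrix of response-window activity.
#' @export
all_inputs_sweep <- function(net, stride = 400, window = 50, blank = 150,
                             stim_weight = DEFAULT_STIM_WEIGHT, tie_seed = 1,
                             genome = NULL, stim_offsets = stimulation_burst()) {
  idx <- seq.int(1L, 160000L, by = as.integer(stride))
  k <- idx - 1L
  bins <- cbind((k %/% 8000L) %% 20L, (k %/% 400L) %% 20L,
                (k %/% 20L) %% 20L, k %% 20L)  # 0-based
  sp <- make_session(net, genome)
  out <- sess_sweep(sp, bins, window, blank, stim_weight, tie_seed, stim_offsets)
  if (any(out$residual > 0))
    warning(sum(out$residual > 0), " blank periods contained residual spikes; ",
            "increase `blank`")
  records <- tibble::tibble(
    combo = idx,
    bin_position = bins[, 1] + 1L, bin_velocity = bins[, 2] + 1L,
    bin_angle = bins[, 3] + 1L, bin_angular_velocity = bins[, 4] + 1L,
    n_left = out$n_left, n_right = out$n_right,
    action = ifelse(out$action == 0L, "left", "right"),
    tie = out$tie, residual = out$residual
  )
  structure(list(records = records, active = out$active,
                 stride = stride, n_neurons = ncol(out$active)),
            class = "sweep_records")
}

#' Action-selectivity map
#'
#' For each of the 80 sensory neurons, restricts the sweep to the records
#' in which that neuron was activated, and scores every network neuron by
#' its signed participation: `p_L` = fraction of left-action records in
#' which it spiked, `p_R` likewise for right. The map entry is `+p_L` when
#' the neuron participates at least as often in left moves, otherwise
#' `-p_R` (positive = Move-Left preference, negative = Move-Right). A
#' neuron never active under that sensory activation scores 0.
#'
#' @param sweep A [all_inputs_sweep()] result.
#' @return An 80 x n_neurons matrix with entries in `[-1, 1]`.
#' @export
action_selectivity <- function(sweep) {
  rec <- sweep$records
  bins <- as.matrix(rec[, c("bin_position", "bin_velocity", "bin_angle",
                            "bin_angular_velocity")])
  map <- matrix(0, nrow = 80, ncol = sweep$n_neurons)
  for (s in 1:80) {
    var <- (s - 1) %/% 20 + 1
    bin <- (s - 1) %% 20 + 1
    rows <- bins[, var] == bin
    left <- rows & rec$action == "left"
    right <- rows & rec$action == "right"
    p_l <- if (any(left)) colMeans(sweep$active[left, , drop = FALSE]) else numeric(sweep$n_neurons)
    p_r <- if (any(right)) colMeans(sweep$active[right, , drop = FALSE]) else numeric(sweep$n_neurons)
    map[s, ] <- ifelse(p_l >= p_r, p_l, -p_r)
  }
  map
}

#' Sensory-motor maps over variable pairs
#'
#' For each of the 6 pairs of sensory variables and each of the 20 x 20
#' joint bin values, the probability of Move-Left, Stay and Move-Right over
#' all sweep records matching that pair (marginalizing the other two
#' variables). "Stay" is a winner-take-all tie. The three probabilities sum
#' to 1 in every populated cell.
#'
#' @param sweep A [all_inputs_sweep()] result.
#' @return A named list of 6 arrays of dimension `20 x 20 x 3`
#'   (`left`/`stay`/`right` slices).
#' @export
sensory_motor_map <- function(sweep) {
  rec <- sweep$records
  vars <- c("position", "velocity", "angle", "angular_velocity")
  bins <- as.matrix(rec[, paste0("bin_", vars)])
  category <- ifelse(rec$tie, "stay", rec$action)
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    arr <- array(0, dim = c(20, 20, 3),
                 dimnames = list(NULL, NULL, c("left", "stay", "right")))
    for (cat_i in 1:3) {
      cat <- c("left", "stay", "right")[cat_i]
      tab <- table(factor(bins[category == cat, i], levels = 1:20),
                   factor(bins[category == cat, j], levels = 1:20))
      arr[, , cat_i] <- as.matrix(tab)
    }
    tot <- arr[, , 1] + arr[, , 2] + arr[, , 3]
    for (cat_i in 1:3) arr[, , cat_i] <- ifelse(tot > 0, arr[, , cat_i] / tot, 0)
    out[[paste(vars[i], vars[j], sep = "_x_")]] <- arr
  }
  out
}
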