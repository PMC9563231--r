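#' Neuron model parameters per cell type
#'
#' Three reduced integrate-and-fire cell classes are used: excitatory (`E`),
#' fast-spiking inhibitory (`I`), and low-threshold-activated inhibitory
#' (`IL`). Each row gives the resting potential, spiking threshold,
#' depolarization-blockade voltage, absolute refractory period, relative
#' refractory weight and time constant, and the after-hyperpolarization
#' increment and time constant.
#'
#' @return A tibble with one row per cell type. Voltages are in mV, time
#'   constants in ms, `w_rr` is unitless.
#' @export
#' @examples
#' cell_types()
cell_types <- function() {
  tibble::tibble(
    cell_type     = c("E", "I", "IL"),
    v_rest        = c(-65, -63, -65),
    v_thresh      = c(-40, -40, -47),
    v_block       = c(-25, -10, -10),
    tau_abs_refrac = c(5, 2.5, 2.5),
    w_rel_refrac  = c(0.75, 0.25, 0.25),
    tau_rel_refrac = c(8, 1.5, 1.5),
    delta_v_ahp   = c(1, 0.5, 0.5),
    tau_ahp       = c(400, 50, 50)
  )
}

#' Synapse channel parameters
#'
#' Four synaptic channels: AMPA (`AM2`) and NMDA (`NM2`) are excitatory with a
#' 0 mV reversal potential; somatic GABAA (`GA`) and dendritic GABAA (`GA2`)
#' are inhibitory with a -80 mV reversal. Each channel holds one
#' exponentially decaying voltage state variable per neuron; inhibitory
#' channels enter the membrane potential with negative sign so that all
#' synaptic weights stay non-negative.
#'
#' @return A tibble with one row per channel kind (`e_syn` mV absolute,
#'   `tau_decay` ms, `sign` +/- 1).
#' @export
#' @examples
#' synapse_channels()
synapse_channels <- function() {
  tibble::tibble(
    kind      = c("AM2", "NM2", "GA", "GA2"),
    e_syn     = c(0, 0, -80, -80),
    tau_decay = c(20, 300, 10, 20),
    sign      = c(1, 1, -1, -1)
  )
}

# Channel kind -> integer code used at the C++ boundary.
channel_code <- function(kind) {
  code <- match(kind, c("AM2", "NM2", "GA", "GA2"))
  if (anyNA(code)) stop("unknown synapse channel kind: ", paste(kind[is.na(code)], collapse = ", "))
  code
}

# Matrix forms consumed by the engine.
cell_param_matrix <- function() {
  ct <- cell_types()
  as.matrix(ct[, -1])
}

chan_param_matrix <- function() {
  ch <- synapse_channels()
  as.matrix(ch[, -1])
}

cell_params_row <- function(cell_type = c("E", "I", "IL")) {
  cell_type <- match.arg(cell_type)
  ct <- cell_types()
  as.list(ct[ct$cell_type == cell_type, -1])
}
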