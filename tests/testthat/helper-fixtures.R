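# Shared fixtures, built once per test run.

.fixtures <- new.env()

fixture_net <- function(seed = 6, plastic = c("ES_EA", "EA_EM")) {
  key <- paste0("net-", seed, "-", paste(plastic, collapse = "+"))
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build_network(seed, plastic_pathways = plastic)
  .fixtures[[key]]
}

cell_E_vec <- function() unlist(as.list(cell_types()[1, -1]))
cell_vec <- function(type) unlist(as.list(cell_types()[cell_types()$cell_type == type, -1]))
chan_mat <- function() as.matrix(synapse_channels()[, -1])

# A synthetic sweep_records object with known bins, actions and activity,
# for testing the map computations as pure functions.
synthetic_sweep <- function(records, active) {
  structure(list(records = records, active = active, stride = NA,
                 n_neurons = ncol(active)), class = "sweep_records")
}
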