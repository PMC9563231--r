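#' Default population layout
#'
#' Three layers: a sensory layer (`ES`, 80 excitatory neurons in four
#' 20-neuron groups encoding position, velocity, angle and angular
#' velocity), an association layer (`EA` 40 excitatory, `IA` 10 fast-spiking
#' inhibitory, `IAL` 10 low-threshold inhibitory) and a motor layer (`EM_L`
#' and `EM_R` with 20 excitatory neurons each, plus `IM` and `IML` with 10
#' inhibitory neurons each). Global neuron ids are assigned contiguously in
#' this order.
#'
#' @return A tibble with columns `name`, `size`, `cell_type`, `start`, `end`.
#' @export
default_populations <- function() {
  pops <- tibble::tibble(
    name = c("ES", "EA", "IA", "IAL", "EM_L", "EM_R", "IM", "IML"),
    size = c(80L, 40L, 10L, 10L, 20L, 20L, 10L, 10L),
    cell_type = c("E", "E", "I", "IL", "E", "E", "I", "IL")
  )
  pops$end <- cumsum(pops$size)
  pops$start <- pops$end - pops$size + 1L
  pops[, c("name", "size", "cell_type", "start", "end")]
}

#' Default connectivity table
#'
#' One row per (pathway, channel): the presynaptic and postsynaptic
#' populations, the connection convergence (the fixed number of presynaptic
#' sources wired into each postsynaptic neuron; see [build_network()]),
#' the synapse channel, the initial weight, and whether the synapse is
#' plastic. `EM` denotes the pooled `EM_L + EM_R` population. Excitatory
#' pathways carry paired AMPA (`AM2`) and NMDA (`NM2`) synapses from the
#' same sources; only the AMPA synapses of the `ES -> EA` and `EA -> EM`
#' pathways are plastic.
#'
#' @return A tibble with columns `pre_pop`, `post_pop`, `convergence`,
#'   `channel`, `weight`, `plastic`.
#' @export
default_connectivity <- function() {
  tibble::tibble(
    pre_pop = c("ES", "ES", "EA", "EA", "EA", "EA", "EA", "EA",
                "IA", "IA", "IA", "IAL", "IAL", "IAL",
                "EM", "EM", "EM", "EM", "IM", "IM", "IM", "IML", "IML", "IML"),
    post_pop = c("EA", "EA", "IA", "IA", "IAL", "IAL", "EM", "EM",
                 "EA", "IA", "IAL", "EA", "IA", "IAL",
                 "IM", "IM", "IML", "IML", "EM", "IM", "IML", "EM", "IM", "IML"),
    convergence = c(25L, 25L, 15L, 15L, 15L, 15L, 20L, 20L,
                    4L, 1L, 2L, 4L, 2L, 1L,
                    16L, 16L, 16L, 16L, 4L, 1L, 2L, 4L, 2L, 1L),
    channel = c("AM2", "NM2", "AM2", "NM2", "AM2", "NM2", "AM2", "NM2",
                "GA", "GA", "GA", "GA2", "GA2", "GA2",
                "AM2", "NM2", "AM2", "NM2", "GA", "GA", "GA", "GA2", "GA2", "GA2"),
    weight = c(10.0, 0.196, 5.85, 0.0585, 5.94, 0.294, 6.5, 0.1,
               18.0, 4.5, 4.5, 5.0, 2.25, 5.5,
               5.85, 0.0585, 2.94, 0.294, 18.0, 4.5, 4.5, 5.0, 2.25, 5.5),
    plastic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                rep(FALSE, 16))
  )
}

# Resolve a population name (incl. pooled "EM") to global neuron ids.
population_ids <- function(populations, name) {
  if (name == "EM") {
    return(c(population_ids(populations, "EM_L"), population_ids(populations, "EM_R")))
  }
  row <- populations[populations$name == name, ]
  if (nrow(row) != 1) stop("unknown population: ", name)
  seq.int(row$start, row$end)
}

#' Build a seeded spiking network
#'
#' Constructs the three-layer network. `convergence` follows the
#' simulator-native in-degree convention: for every connectivity pathway
#' and every postsynaptic neuron, `convergence` distinct presynaptic
#' sources are sampled uniformly without replacement (self-connections
#' excluded), with one synapse per listed channel from the same source
#' set. This reading is forced by the connectivity table itself — several
#' excitatory-to-inhibitory rows list a convergence larger than their
#' 10-neuron target population, which rules out a fixed number of
#' postsynaptic targets per source — and it equalizes the summed input
#' every motor neuron receives, which is what keeps untrained networks at
#' random-policy performance regardless of the wiring seed.
#' Somatic-channel delays (`AM2`, `NM2`, `GA`) are drawn Uniform(1.8, 2.2)
#' ms; dendritic (`GA2`) delays Uniform(3, 12) ms. Wiring and delays use
#' independent RNG substreams derived from `wiring_seed`, so an identical
#' seed yields a byte-identical network.
#'
#' The ordered positions of plastic synapses define the genome: the vector
#' of plastic weights manipulated by the evolutionary strategy and by
#' STDP-RL. Per-neuron initial plastic reception totals (summed incoming
#' plastic weight) and transmission totals (summed outgoing plastic weight)
#' are recorded at build time for the homeostatic normalization mechanisms.
#'
#' @param wiring_seed Integer seed naming the network instance.
#' @param connectivity Connectivity table, defaults to [default_connectivity()].
#' @param plastic_pathways Which pathways keep their plasticity flag:
#'   any subset of `c("ES_EA", "EA_EM")`.
#' @return An object of class `snn_network`.
#' @export
#' @examples
#' net <- build_network(6)
#' length(extract_genome(net))   # 1800
build_network <- function(wiring_seed,
                          connectivity = default_connectivity(),
                          plastic_pathways = c("ES_EA", "EA_EM")) {
  pops <- default_populations()
  n_neurons <- sum(pops$size)
  conn <- connectivity
  conn$pathway <- paste(conn$pre_pop, conn$post_pop, sep = "_")
  conn$plastic <- conn$plastic & conn$pathway %in% plastic_pathways

  # group channels sharing a (pre_pop, post_pop) row: paired channels land
  # on the same sampled targets
  groups <- unique(conn[, c("pre_pop", "post_pop", "convergence")])
  pre_l <- list(); post_l <- list(); chan_l <- list()
  w_l <- list(); plast_l <- list(); path_l <- list()
  k <- 0L
  with_seed(substream_seed(wiring_seed, "wiring"), {
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      rows <- conn[conn$pre_pop == g$pre_pop & conn$post_pop == g$post_pop, ]
      pre_ids <- population_ids(pops, g$pre_pop)
      post_ids <- population_ids(pops, g$post_pop)
      if (g$convergence > length(pre_ids) - (g$pre_pop == g$post_pop))
        stop("convergence exceeds source population size for ",
             g$pre_pop, " -> ", g$post_pop)
      for (p in post_ids) {
        sources <- sort(sample(setdiff(pre_ids, p), g$convergence))
        for (ri in seq_len(nrow(rows))) {
          k <- k + 1L
          pre_l[[k]] <- sources
          post_l[[k]] <- rep.int(p, g$convergence)
          chan_l[[k]] <- rep.int(rows$channel[ri], g$convergence)
          w_l[[k]] <- rep.int(rows$weight[ri], g$convergence)
          plast_l[[k]] <- rep.int(rows$plastic[ri], g$convergence)
          path_l[[k]] <- rep.int(rows$pathway[ri], g$convergence)
        }
      }
    }
  })
  syn <- tibble::tibble(
    pre = unlist(pre_l), post = unlist(post_l), channel = unlist(chan_l),
    weight = unlist(w_l), delay = NA_real_, plastic = unlist(plast_l),
    pathway = unlist(path_l)
  )
  somatic <- syn$channel %in% c("AM2", "NM2", "GA")
  with_seed(substream_seed(wiring_seed, "delays"), {
    syn$delay[somatic] <- runif(sum(somatic), 1.8, 2.2)
    syn$delay[!somatic] <- runif(sum(!somatic), 3, 12)
  })

  plastic_idx <- which(syn$plastic)
  init_recept <- rep(0, n_neurons)
  init_trans <- rep(0, n_neurons)
  for (i in plastic_idx) {
    init_recept[syn$post[i]] <- init_recept[syn$post[i]] + syn$weight[i]
    init_trans[syn$pre[i]] <- init_trans[syn$pre[i]] + syn$weight[i]
  }

  structure(list(
    populations = pops,
    synapses = syn,
    plastic_idx = plastic_idx,
    plastic_pathway = syn$pathway[plastic_idx],
    plastic_post = syn$post[plastic_idx],
    plastic_pre = syn$pre[plastic_idx],
    initial_reception_totals = init_recept,
    initial_transmission_totals = init_trans,
    wiring_seed = wiring_seed,
    connectivity = conn
  ), class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network> wiring seed", x$wiring_seed, "\n")
  cat(" ", sum(x$populations$size), "neurons in", nrow(x$populations), "populations;",
      nrow(x$synapses), "synapses,", length(x$plastic_idx), "plastic\n")
  invisible(x)
}

#' Extract the plastic-weight genome
#'
#' @param net An `snn_network`.
#' @return Numeric vector of plastic synaptic weights in genome order.
#' @export
extract_genome <- function(net) {
  net$synapses$weight[net$plastic_idx]
}

#' Replace the plastic-weight genome
#'
#' @param net An `snn_network`.
#' @param genome Numeric vector, same length and order as
#'   [extract_genome()]; all entries must be non-negative.
#' @return The network with plastic weights replaced; non-plastic weights
#'   are untouched.
#' @export
set_genome <- function(net, genome) {
  if (length(genome) != length(net$plastic_idx)) stop("genome length mismatch")
  if (any(genome < 0)) stop("negative genome entries")
  net$synapses$weight[net$plastic_idx] <- genome
  net
}

#' Write a network checkpoint as JSON
#'
#' The checkpoint holds the wiring seed, the full synapse list and the
#' genome — sufficient for bit-exact reload with [read_network_json()].
#'
#' @param net An `snn_network`.
#' @param path Output file path.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    wiring_seed = net$wiring_seed,
    populations = net$populations,
    synapses = net$synapses,
    plastic_idx = net$plastic_idx,
    initial_reception_totals = net$initial_reception_totals,
    initial_transmission_totals = net$initial_transmission_totals
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network checkpoint written by [write_network_json()]
#'
#' @param path JSON file path.
#' @return An `snn_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- tibble::as_tibble(obj$synapses)
  plastic_idx <- as.integer(obj$plastic_idx)
  structure(list(
    populations = tibble::as_tibble(obj$populations),
    synapses = syn,
    plastic_idx = plastic_idx,
    plastic_pathway = syn$pathway[plastic_idx],
    plastic_post = syn$post[plastic_idx],
    plastic_pre = syn$pre[plastic_idx],
    initial_reception_totals = as.numeric(obj$initial_reception_totals),
    initial_transmission_totals = as.numeric(obj$initial_transmission_totals),
    wiring_seed = obj$wiring_seed,
    connectivity = NULL
  ), class = "snn_network")
}
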