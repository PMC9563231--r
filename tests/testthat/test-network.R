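test_that("plastic pathway counts match the connectivity table", {
  net <- fixture_net(6)
  es <- net$plastic_pathway == "ES_EA"
  em <- net$plastic_pathway == "EA_EM"
  expect_equal(sum(es), 40 * 25)   # each of 40 EA receives 25 ES sources
  expect_equal(sum(em), 40 * 20)   # each pooled-EM neuron receives 20 EA sources
  g <- extract_genome(net)
  expect_length(g, 1800)
  expect_true(all(g[es] == 10.0))
  expect_true(all(g[em] == 6.5))
})

test_that("restricting plasticity to the motor pathway gives an 800-genome", {
  net <- fixture_net(6, plastic = "EA_EM")
  expect_length(extract_genome(net), 800)
  expect_true(all(extract_genome(net) == 6.5))
})

test_that("identical wiring seed reproduces the network exactly", {
  a <- build_network(3)
  b <- build_network(3)
  expect_identical(a$synapses, b$synapses)
  # a different seed draws different sources (post ids are structural)
  expect_false(identical(build_network(4)$synapses$pre, a$synapses$pre))
})

test_that("every neuron receives its exact convergence with no self-connections", {
  net <- fixture_net(6)
  syn <- net$synapses
  expect_true(all(syn$pre != syn$post))
  es_ea <- syn[syn$pathway == "ES_EA" & syn$channel == "AM2", ]
  expect_true(all(table(es_ea$post) == 25))
  expect_true(all(!duplicated(es_ea[, c("pre", "post")])))
  ea_em <- syn[syn$pathway == "EA_EM" & syn$channel == "AM2", ]
  expect_true(all(table(ea_em$post) == 20))
  # pooled EM: every neuron of both subpopulations is wired
  expect_setequal(unique(ea_em$post), 141:180)
  # paired channels share sources: NM2 rows duplicate the AM2 wiring
  es_ea_nm <- syn[syn$pathway == "ES_EA" & syn$channel == "NM2", ]
  expect_identical(es_ea_nm[, c("pre", "post")], es_ea[, c("pre", "post")])
  # inhibitory-target rows whose convergence exceeds the population size
  ea_ia <- syn[syn$pathway == "EA_IA" & syn$channel == "AM2", ]
  expect_true(all(table(ea_ia$post) == 15))
})

test_that("delays fall in the somatic and dendritic sampling ranges", {
  syn <- fixture_net(6)$synapses
  som <- syn$channel %in% c("AM2", "NM2", "GA")
  expect_true(all(syn$delay[som] >= 1.8 & syn$delay[som] <= 2.2))
  expect_true(all(syn$delay[!som] >= 3 & syn$delay[!som] <= 12))
})

test_that("genome round-trips and validates", {
  net <- fixture_net(6)
  expect_identical(set_genome(net, extract_genome(net)), net)
  expect_error(set_genome(net, c(1, 2)), "length mismatch")
  expect_error(set_genome(net, rep(-1, 1800)), "negative")
  g2 <- runif(1800)
  expect_equal(extract_genome(set_genome(net, g2)), g2)
  # non-plastic weights untouched
  net2 <- set_genome(net, g2)
  expect_identical(net2$synapses$weight[-net2$plastic_idx],
                   net$synapses$weight[-net$plastic_idx])
})

test_that("initial reception and transmission totals are consistent", {
  net <- fixture_net(6)
  expect_equal(sum(net$initial_reception_totals),
               sum(net$initial_transmission_totals))
  expect_equal(sum(net$initial_reception_totals), 1000 * 10 + 800 * 6.5)
  # fixed in-degree: uniform reception totals within each plastic layer
  expect_true(all(net$initial_reception_totals[81:120] == 25 * 10))
  expect_true(all(net$initial_reception_totals[141:180] == 20 * 6.5))
  expect_true(all(net$initial_reception_totals[1:80] == 0))
})

test_that("a JSON checkpoint reloads bit-exactly", {
  net <- fixture_net(6)
  path <- tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$synapses$weight, net$synapses$weight)
  expect_equal(back$synapses$delay, net$synapses$delay)
  expect_identical(as.integer(back$synapses$pre), as.integer(net$synapses$pre))
  expect_equal(back$initial_reception_totals, net$initial_reception_totals)
  unlink(path)
})
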