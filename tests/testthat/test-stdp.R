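test_that("tagging requires a causal pair within the window, boundary closed", {
  p <- rl_params(windhebb = 20, lenhebb = 1000)
  tag <- on_spike_pair(100, 105, p)
  expect_equal(tag$tagged_at, 105)
  expect_equal(tag$expires_at, 1105)
  expect_null(on_spike_pair(105, 100, p))        # acausal
  expect_null(on_spike_pair(100, 100, p))        # simultaneous
  expect_equal(on_spike_pair(100, 120, p)$expires_at, 1120)  # closed boundary
  expect_null(on_spike_pair(100, 120.001, p))
})

test_that("targeted-both delivery scales acting, opposite and upstream synapses", {
  net <- fixture_net(6)
  p <- rl_params(targeted_mode = "targeted_both", opp_em_attenuation = 0.5,
                 non_motor_rl = FALSE, hebbwt = 0.01)
  tags <- clear_tags(net)
  em <- net$plastic_pathway == "EA_EM"
  onto_l <- em & net$plastic_post %in% 141:160
  onto_r <- em & net$plastic_post %in% 161:180
  # tag a handful of synapses on each side plus an untagged control
  tag_l <- which(onto_l)[1:5]; tag_r <- which(onto_r)[1:5]
  tags[c(tag_l, tag_r)] <- 100
  out <- apply_critic(net, tags, 0.5, "left", 50, p, homeo = NULL)
  dw <- extract_genome(out) - extract_genome(net)
  expect_equal(dw[tag_l], rep(0.01 * 0.5, 5))            # +0.005
  expect_equal(dw[tag_r], rep(-0.01 * 0.5 * 0.5, 5))     # -0.0025
  expect_equal(sum(dw != 0), 10)                          # untagged untouched
})

test_that("targeted-main leaves the opposite subpopulation unchanged", {
  net <- fixture_net(6)
  p <- rl_params(targeted_mode = "targeted_main", non_motor_rl = FALSE)
  tags <- rep(1e9, length(net$plastic_idx))  # everything tagged
  out <- apply_critic(net, tags, 1, "right", 0, p, homeo = NULL)
  dw <- extract_genome(out) - extract_genome(net)
  onto_l <- net$plastic_pathway == "EA_EM" & net$plastic_post %in% 141:160
  onto_r <- net$plastic_pathway == "EA_EM" & net$plastic_post %in% 161:180
  expect_true(all(dw[onto_l] == 0))
  expect_equal(dw[onto_r], rep(p$hebbwt, sum(onto_r)))
  expect_true(all(dw[net$plastic_pathway == "ES_EA"] == 0))  # non_motor off
})

test_that("non-motor delivery reaches sensory-association synapses when enabled", {
  net <- fixture_net(6)
  p <- rl_params(targeted_mode = "non_targeted", non_motor_rl = TRUE,
                 non_motor_attenuation = 0.5)
  s <- delivery_scaling(net, "left", p)
  expect_true(all(s[net$plastic_pathway == "ES_EA"] == 0.5))
  expect_true(all(s[net$plastic_pathway == "EA_EM"] == 1))
})

test_that("zero critic, expired tags, and the weight floor behave correctly", {
  net <- fixture_net(6)
  tags <- rep(1e9, length(net$plastic_idx))
  # zero critic: no changes
  out <- apply_critic(net, tags, 0, "left", 0, rl_params(), homeo = NULL)
  expect_equal(extract_genome(out), extract_genome(net))
  # expired tags: delivery after expiry is a no-op
  tags2 <- clear_tags(net); tags2[1] <- 100
  out <- apply_critic(net, tags2, 1, "left", 200, rl_params(), homeo = NULL)
  expect_equal(extract_genome(out), extract_genome(net))
  # floor at zero under a massive punishment
  p_big <- rl_params(hebbwt = 1000, targeted_mode = "non_targeted")
  out <- apply_critic(net, tags, -1, "left", 0, p_big, homeo = NULL)
  expect_true(all(extract_genome(out) >= 0))
  expect_true(any(extract_genome(out) == 0))
})

test_that("update magnitude is constant regardless of tag age", {
  net <- fixture_net(6)
  p <- rl_params(targeted_mode = "non_targeted", non_motor_rl = FALSE)
  k <- which(net$plastic_pathway == "EA_EM")[1]
  fresh <- clear_tags(net); fresh[k] <- 2000    # tagged just now
  old <- clear_tags(net); old[k] <- 100         # tagged long ago, still live
  d1 <- extract_genome(apply_critic(net, fresh, 0.7, "left", 99, p, homeo = NULL)) -
    extract_genome(net)
  d2 <- extract_genome(apply_critic(net, old, 0.7, "left", 99, p, homeo = NULL)) -
    extract_genome(net)
  expect_identical(d1, d2)
  expect_equal(d1[k], p$hebbwt * 0.7)
})

test_that("the engine's tag-and-deliver path matches the reference implementation", {
  net <- fixture_net(6)
  rl <- rl_params()
  homeo <- homeostasis_params()
  sp <- make_session(net)
  sess_set_tagging(sp, TRUE, rl$windhebb, rl$lenhebb)
  rf <- build_receptive_fields()
  # stimulate a few windows to create real spike-pair tags
  st <- cartpole_reset(5)
  for (i in 1:5) sess_run_window(sp, encode_state(st, rf), 35, 50)
  tags <- sess_tag_expiry(sp)
  expect_gt(sum(tags > 0), 0)
  now <- sess_time(sp)
  s <- delivery_scaling(net, "left", rl)
  sess_apply_critic(sp, s, 0.6, rl$hebbwt, now, TRUE,
                    homeo$out_balance_min, homeo$out_balance_max)
  ref <- apply_critic(net, tags, 0.6, "left", now, rl, homeo)
  expect_equal(sess_get_weights(sp), extract_genome(ref), tolerance = 1e-12)
})

test_that("a short training run improves performance and keeps weights valid", {
  net <- fixture_net(6)
  fit <- run_stdp_training(net, duration_s = 250, seed = 1)
  expect_s3_class(fit$episodes, "stdp_log")
  expect_equal(fit$steps, 5000)
  g <- extract_genome(fit$network)
  expect_true(all(g >= 0))
  expect_false(identical(g, extract_genome(net)))  # learning happened
  # reception totals conserved at their (drifted) targets after training
  cur <- rowsum(g, fit$network$plastic_post)
  tgt <- fit$reception_targets[as.integer(rownames(cur))]
  expect_true(all(abs(cur[, 1] - tgt) < 1e-6 | cur[, 1] == 0))
})
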