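test_that("synaptic and AHP decays follow the closed-form exponential", {
  st <- neuron_state("E")
  st$v_syn[["AM2"]] <- 10
  out <- decay_to(st, 20)
  expect_equal(out$v_syn[["AM2"]], 10 / exp(1))

  st <- neuron_state("E")
  st$v_syn[["NM2"]] <- 6
  st$v_ahp <- 2
  out <- decay_to(st, 150)
  expect_equal(out$v_syn[["NM2"]], 6 * exp(-150 / 300))
  expect_equal(out$v_ahp, 2 * exp(-150 / 400))
})

test_that("zero elapsed time is the identity and rest is a fixed point", {
  st <- neuron_state("E")
  st$v_syn[["GA"]] <- 4
  expect_identical(decay_to(st, 0), st)

  st <- neuron_state("I")
  for (t in c(1, 10, 500)) expect_equal(membrane_potential(decay_to(st, t)), -63)
})

test_that("time regression is rejected", {
  st <- decay_to(neuron_state("E"), 10)
  expect_error(decay_to(st, 5), "time regression")
})

test_that("an excitatory event at rest depolarizes by exactly its weight", {
  out <- deliver_event(neuron_state("E"), "AM2", 10, 1)
  expect_equal(membrane_potential(out$state), -55)
  expect_false(out$fired)
})

test_that("driving force vanishes at the reversal potential", {
  # push v_syn so v_m sits exactly at the AMPA reversal (0 mV absolute)
  st <- neuron_state("E")
  st$v_syn[["AM2"]] <- 65
  out <- deliver_event(st, "AM2", 12, 0)
  expect_equal(out$state$v_syn[["AM2"]], 65)   # dV = 0
})

test_that("depolarization block suppresses spiking above v_block", {
  out <- deliver_event(neuron_state("E"), "AM2", 45, 1)  # v_m = -20 > -25
  expect_false(out$fired)
  expect_equal(membrane_potential(out$state), -20)
})

test_that("a spike raises the threshold by w_rr * (v_block - v_thresh)", {
  out <- deliver_event(neuron_state("E"), "AM2", 30, 1)  # v_m = -35, fires
  expect_true(out$fired)
  expect_equal(out$state$v_thresh, -40 + 0.75 * (-25 - (-40)))  # -28.75
  expect_equal(out$state$spike_times, 1)
  # synaptic state resets after the spike; AHP increments
  expect_true(all(out$state$v_syn == 0))
  expect_equal(out$state$v_ahp, 1)
})

test_that("negative weights and unknown channels are rejected", {
  expect_error(deliver_event(neuron_state("E"), "AM2", -1, 1), "negative")
  expect_error(deliver_event(neuron_state("E"), "XX", 1, 1), "unknown")
})

test_that("no two spikes are closer than the absolute refractory period", {
  set.seed(11)
  for (type in c("E", "I", "IL")) {
    cv <- cell_vec(type)
    n_multi <- 0
    for (r in 1:20) {
      t <- sort(runif(200, 0, 400))
      out <- neuron_trajectory_event(cv, chan_mat(), t,
                                     rep(1L, 200), runif(200, 5, 20))
      if (length(out$spike_times) > 1) {
        n_multi <- n_multi + 1
        expect_gte(min(diff(out$spike_times)), cv[["tau_abs_refrac"]])
      }
    }
    expect_gt(n_multi, 0)   # the property was actually exercised
  }
})

test_that("the instantaneous threshold never falls below its baseline", {
  set.seed(12)
  st <- neuron_state("E")
  ts <- sort(runif(60, 0, 300))
  for (i in seq_along(ts)) {
    st <- deliver_event(st, sample(c("AM2", "NM2", "GA"), 1), runif(1, 0, 30), ts[i])$state
    expect_gte(st$v_thresh, st$params$v_thresh - 1e-12)
  }
})

test_that("with no input the membrane returns to rest monotonically", {
  st <- deliver_event(neuron_state("E"), "AM2", 20, 0)$state
  devs <- sapply(seq(5, 200, by = 5), function(t)
    abs(membrane_potential(decay_to(st, t)) - st$params$v_rest))
  expect_true(all(diff(devs) <= 1e-12))
  expect_lt(devs[length(devs)], 0.01)
})

test_that("pure-R and engine event-driven neuron paths agree exactly", {
  set.seed(21)
  kinds <- c("AM2", "NM2", "GA", "GA2")
  for (type in c("E", "I", "IL")) {
    m <- 40
    t <- sort(runif(m, 0, 120))
    ch <- sample(1:4, m, replace = TRUE)
    w <- runif(m, 0, 20)
    cpp <- neuron_trajectory_event(cell_vec(type), chan_mat(), t, ch, w)
    st <- neuron_state(type)
    vm <- numeric(m); fired <- logical(m)
    for (i in seq_len(m)) {
      o <- deliver_event(st, kinds[ch[i]], w[i], t[i])
      st <- o$state; vm[i] <- membrane_potential(st); fired[i] <- o$fired
    }
    expect_equal(vm, cpp$vm, tolerance = 1e-12)
    expect_identical(fired, as.logical(cpp$fired))
  }
})
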