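test_that("frozen evaluation is deterministic and never mutates the network", {
  net <- fixture_net(6)
  ds <- episode_datasets(42, n = 10)
  g0 <- extract_genome(net)
  a <- evaluate_frozen(net, ds$testing)
  b <- evaluate_frozen(net, ds$testing)
  expect_identical(a$steps, b$steps)
  expect_identical(extract_genome(net), g0)
  expect_true(all(a$steps >= 1 & a$steps <= 500))
  expect_equal(a$mean, mean(a$steps))
  expect_equal(a$median, median(a$steps))
  # a different tie-break seed may change tied decisions but stays in range
  c_ <- evaluate_frozen(net, ds$testing, tie_seed = 2)
  expect_true(all(c_$steps >= 1 & c_$steps <= 500))
})

test_that("recorded episodes expose actions, motor counts and states", {
  net <- fixture_net(6)
  out <- run_episode(net, c(0.01, 0, -0.02, 0), record = TRUE)
  expect_length(out$actions, out$steps)
  expect_length(out$n_left, out$steps)
  expect_equal(dim(out$states), c(4, out$steps))
  expect_true(all(out$actions %in% c(0L, 1L)))
  expect_lte(out$steps, 500)
})

test_that("performance reports bind frozen evaluations into a tidy table", {
  net <- fixture_net(6)
  ds <- episode_datasets(42, n = 5)
  ev <- evaluate_frozen(net, ds$testing)
  rpt <- performance_report(initial = ev, trained = ev)
  expect_equal(rpt$model, c("initial", "trained"))
  expect_equal(rpt$mean_steps, rep(ev$mean, 2))
  expect_equal(rpt$n_episodes, rep(5, 2))
})

test_that("the all-inputs sweep enumerates strided combos and records actions", {
  net <- fixture_net(6)
  sw <- all_inputs_sweep(net, stride = 2000)
  expect_equal(nrow(sw$records), 80)
  expect_equal(dim(sw$active), c(80, 200))
  expect_true(all(sw$records$action %in% c("left", "right")))
  # stimulated sensory neurons are always active in their own record
  for (r in c(1, 40, 80)) {
    bins <- unlist(sw$records[r, c("bin_position", "bin_velocity",
                                   "bin_angle", "bin_angular_velocity")])
    ids <- (0:3) * 20 + bins
    expect_true(all(sw$active[r, ids]))
  }
  # blanks prevented leakage between activations
  expect_true(all(sw$records$residual == 0))
  # lexicographic order: first record is bin 1 everywhere
  expect_equal(unname(unlist(sw$records[1, 2:5])), c(1, 1, 1, 1))
  # stride of 20^4 yields exactly one record
  expect_equal(nrow(all_inputs_sweep(net, stride = 160000)$records), 1)
})

test_that("an untrained network decides roughly symmetrically across the sweep", {
  net <- fixture_net(6)
  sw <- all_inputs_sweep(net, stride = 500)
  p_left <- mean(sw$records$action == "left")
  expect_gt(p_left, 0.25)
  expect_lt(p_left, 0.75)
})

test_that("action-selectivity entries reproduce the worked participation ratios", {
  # 12 records all containing sensory neuron 1 (bin 1 of variable 1):
  # 6 left moves, 6 right moves, 3 network neurons with known activity
  rec <- tibble::tibble(
    combo = 1:12, bin_position = 1L, bin_velocity = 1L, bin_angle = 1L,
    bin_angular_velocity = 1L,
    n_left = 0L, n_right = 0L,
    action = rep(c("left", "right"), each = 6),
    tie = FALSE, residual = 0L
  )
  active <- matrix(FALSE, 12, 3)
  active[1:3, 1] <- TRUE          # active in 3/6 left, never right -> +0.5
  active[7:12, 2] <- TRUE         # active in all 6 right records  -> -1
  sw <- synthetic_sweep(rec, active)
  m <- action_selectivity(sw)
  expect_equal(m[1, 1], 0.5)
  expect_equal(m[1, 2], -1)
  expect_equal(m[1, 3], 0)        # never active
  expect_true(all(m >= -1 & m <= 1))
  # sensory neurons of other bins have no matching records -> all zero
  expect_true(all(m[2, ] == 0))
})

test_that("sensory-motor maps are proper conditional distributions", {
  set.seed(81)
  n <- 400
  rec <- tibble::tibble(
    combo = 1:n,
    bin_position = sample(1:20, n, TRUE), bin_velocity = sample(1:20, n, TRUE),
    bin_angle = sample(1:20, n, TRUE), bin_angular_velocity = sample(1:20, n, TRUE),
    n_left = 0L, n_right = 0L, action = "left", tie = FALSE, residual = 0L
  )
  # hard-wired rule: angular-velocity bin >= 11 forces RIGHT, else LEFT;
  # a sprinkle of ties becomes "stay"
  rec$action <- ifelse(rec$bin_angular_velocity >= 11, "right", "left")
  rec$tie[1:20] <- TRUE
  sw <- synthetic_sweep(rec, matrix(FALSE, n, 1))
  maps <- sensory_motor_map(sw)
  expect_length(maps, 6)
  m <- maps$angle_x_angular_velocity
  sums <- m[, , 1] + m[, , 2] + m[, , 3]
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
  # the hard-wired association appears in the marginal map: no left moves
  # ever occur for high angular-velocity bins, no right moves for low ones
  expect_true(all(m[, 11:20, "left"] == 0))
  expect_true(all(m[, 1:10, "right"] == 0))
  expect_gt(mean(m[, 11:20, "right"]), 0.5)
  expect_gt(mean(m[, 1:10, "left"]), 0.5)
})

test_that("map computations are pure functions of the sweep records", {
  net <- fixture_net(6)
  sw <- all_inputs_sweep(net, stride = 4000)
  expect_identical(action_selectivity(sw), action_selectivity(sw))
  expect_identical(sensory_motor_map(sw), sensory_motor_map(sw))
})
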