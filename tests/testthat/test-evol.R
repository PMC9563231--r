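test_that("fitness normalization uses the population standard deviation", {
  expect_equal(normalize_fitness(c(10, 20)), c(-1, 1))
  expect_equal(normalize_fitness(c(5, 5, 5)), c(0, 0, 0))  # degenerate
  set.seed(71)
  f <- runif(10, 1, 500)
  n <- normalize_fitness(f)
  expect_equal(mean(n), 0)
  expect_equal(sqrt(mean(n^2)), 1)
  expect_error(normalize_fitness(3), "at least 2")
})

test_that("multiplicative perturbation scales weights and floors at zero", {
  expect_equal(perturb_genome(6.5, 0, 0.1), 6.5)
  expect_equal(perturb_genome(6.5, 1, 0.1), 7.15)
  expect_equal(perturb_genome(6.5, -15, 0.1), 0)   # floored, never negative
  expect_error(perturb_genome(c(1, 2), 1, 0.1), "length mismatch")
})

test_that("the genome update follows the fitness-weighted perturbation average", {
  p <- evol_params(population = 2, sigma = 0.1, alpha = 1)
  eps <- matrix(c(-0.5, 0.5), nrow = 2)
  out <- update_genome(1, eps, c(-1, 1), p)
  expect_equal(out, 1.05)    # factor 1 + 0.1 * ((0.5 + 0.5) / 2)
  # zero normalized fitness: no update
  expect_equal(update_genome(c(1, 2, 3), matrix(rnorm(6), 2), c(0, 0), p), c(1, 2, 3))
  # simultaneous sign flip of eps and N leaves the update invariant
  set.seed(72)
  w <- runif(5); e <- matrix(rnorm(20), 4); n <- rnorm(4)
  p4 <- evol_params(population = 4)
  expect_equal(update_genome(w, e, n, p4), update_genome(w, -e, -n, p4))
  expect_error(update_genome(w, e, n[1:3], p4), "shape mismatch")
})

test_that("weights stay non-negative over many random updates", {
  set.seed(73)
  p <- evol_params(population = 5, sigma = 0.5, alpha = 2)
  w <- runif(100, 0, 10)
  for (i in 1:100) {
    eps <- matrix(rnorm(500), 5)
    w <- update_genome(w, eps, normalize_fitness(rnorm(5)), p)
    expect_true(all(w >= 0))
  }
})

test_that("zero learning rate keeps the genome constant through training", {
  net <- fixture_net(6, plastic = "EA_EM")
  p <- evol_params(population = 3, alpha = 0, iterations = 3)
  fit <- run_evol(net, p, seed = 1, fitness_fn = function(w, i, j) sum(w))
  expect_identical(fit$genome, extract_genome(net))
  expect_equal(nrow(fit$log), 3)
})

test_that("the strategy climbs a known convex fitness surrogate", {
  net <- fixture_net(6, plastic = "EA_EM")
  w0 <- extract_genome(net)
  target <- w0[1:10] * 1.5
  surrogate <- function(w, i, j) -sum((w[1:10] - target)^2)
  p <- evol_params(population = 10, sigma = 0.05, alpha = 1, iterations = 80)
  fit <- run_evol(net, p, seed = 2, fitness_fn = surrogate)
  d0 <- sum((w0[1:10] - target)^2)
  d1 <- sum((fit$genome[1:10] - target)^2)
  expect_lt(d1, 0.1 * d0)
  # mean surrogate fitness improves from start to finish
  expect_gt(mean(tail(fit$log$mean, 10)), mean(head(fit$log$mean, 10)))
})

test_that("zero iterations leave the genome untouched and runs are reproducible", {
  net <- fixture_net(6, plastic = "EA_EM")
  p0 <- evol_params(iterations = 0)
  expect_identical(run_evol(net, p0, seed = 1,
                            fitness_fn = function(w, i, j) 1)$genome,
                   extract_genome(net))
  p2 <- evol_params(population = 4, episodes_per_eval = 2, iterations = 2)
  a <- run_evol(net, p2, seed = 9)
  b <- run_evol(net, p2, seed = 9)
  expect_identical(a$genome, b$genome)
  expect_identical(a$log, b$log)
  expect_true(all(a$log$min >= 1 & a$log$max <= 500))
})
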