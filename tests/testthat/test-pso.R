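# deterministic toy fitness: peaked at w = 0.7 in every dimension
toy_fitness <- function(w) 1 - mean((w - 0.7)^2)

test_that("swarm initialization respects bounds, shapes and seeds", {
  cfg <- pso_config(n_particles = 60, n_iterations = 100)
  st <- init_swarm(cfg, D = 30, toy_fitness, seed = 5)
  expect_equal(dim(st$x), c(60, 30))
  expect_true(all(st$x >= 0 & st$x <= 1))
  expect_true(all(abs(st$v) <= cfg$vmax))
  expect_equal(st$pbest, st$x)
  expect_equal(st$gbest_fit, max(st$fitness))
  expect_equal(st$gbest, st$x[which.max(st$fitness), ])

  st2 <- init_swarm(cfg, D = 30, toy_fitness, seed = 5)
  expect_identical(st, st2)
})

test_that("a converged swarm is a fixed point of the update", {
  cfg <- pso_config(n_particles = 3, n_iterations = 1, c1 = 0.6, c2 = 0.6)
  st <- init_swarm(cfg, D = 4, toy_fitness, seed = 1)
  x0 <- matrix(rep(st$x[1, ], 3), 3, 4, byrow = TRUE)
  st$x <- st$pbest <- x0
  st$v <- matrix(0, 3, 4)
  st$gbest <- x0[1, ]
  f0 <- toy_fitness(x0[1, ])
  st$fitness <- st$pbest_fit <- rep(f0, 3)
  st$gbest_fit <- f0
  out <- pso_step(st, toy_fitness)
  expect_equal(out$x, x0)
  expect_equal(out$v, matrix(0, 3, 4))
  expect_equal(out$t, st$t + 1L)
})

test_that("the position update reproduces the hand-computed rule", {
  # one particle, c1 = c2 = 0, w = 1, v = 0.1, x = 0.5 -> x = 0.6
  cfg <- pso_config(n_particles = 1, n_iterations = 1, inertia = 1,
                    c1 = 0, c2 = 0, vmax = 0.2)
  st <- init_swarm(cfg, D = 1, toy_fitness, seed = 2)
  st$x <- st$pbest <- matrix(0.5, 1, 1)
  st$gbest <- 0.5
  st$v <- matrix(0.1, 1, 1)
  out <- pso_step(st, toy_fitness)
  expect_equal(as.vector(out$x), 0.6)
  expect_equal(as.vector(out$v), 0.1)
})

test_that("with c1 = c2 = 0 and inertia < 1 velocities decay geometrically", {
  cfg <- pso_config(n_particles = 2, n_iterations = 1, inertia = 0.5,
                    c1 = 0, c2 = 0, vmax = 1)
  st <- init_swarm(cfg, D = 3, toy_fitness, seed = 3)
  st$x[] <- 0.5
  st$pbest <- st$x
  st$v[] <- 0.08
  v0 <- st$v
  for (i in 1:4) st <- pso_step(st, toy_fitness)
  expect_equal(st$v, v0 * 0.5^4, tolerance = 1e-12)
})

test_that("positions stay in the box and gbest never degrades", {
  cfg <- pso_config(n_particles = 8, n_iterations = 30, vmax = 0.3,
                    fitness_folds = 2)
  st <- init_swarm(cfg, D = 5, toy_fitness, seed = 7)
  prev <- st$gbest_fit
  for (i in seq_len(cfg$n_iterations)) {
    st <- pso_step(st, toy_fitness)
    expect_true(all(st$x >= 0 & st$x <= 1))
    expect_gte(st$gbest_fit, prev)
    prev <- st$gbest_fit
  }
  expect_equal(st$history, cummax(st$history))
  # the toy optimum at 0.7 is found to reasonable precision
  expect_gt(st$gbest_fit, 0.99)
})

test_that("optimize_weights finds an informative profile column", {
  set.seed(31)
  n <- 300
  y <- rep(c(0L, 1L), each = n / 2)
  profile <- matrix(runif(n * 30), n, 30)
  profile[, 7] <- pmin(pmax(y + rnorm(n, sd = 0.2), 0), 1)
  colnames(profile) <- sprintf("col%02d", 1:30)
  cfg <- pso_config(n_particles = 10, n_iterations = 15, fitness_folds = 5)
  res <- optimize_weights(profile, y, config = cfg, seed = 17)

  expect_length(res$w, 30)
  expect_true(all(res$w >= 0 & res$w <= 1))
  expect_length(res$history, 15)
  expect_equal(res$history, cummax(res$history))
  expect_gte(res$fitness, 0.95)
  # the raw weight of the informative column is confounded with its
  # meta-classifier coefficient (the classifier can rescale whatever
  # weight lets signal through), so the identifiable quantity is the
  # effective weight: weight x coefficient must dominate all columns
  meta <- fit_meta(sweep(profile, 2, res$w, "*"), y)
  b <- meta_coefficients(meta)[colnames(profile)]
  expect_equal(which.max(abs(b * res$w)), c(col07 = 7L))

  # all-ones weights reproduce the unweighted stacking fitness: compare
  # fitness(1) against a CV loop with no weighting step at all
  folds <- stratified_folds(y, cfg$fitness_folds, seed = 17)
  pred <- numeric(n)
  for (f in seq_len(cfg$fitness_folds)) {
    hold <- folds == f
    m <- fit_meta(profile[!hold, ], y[!hold])
    pred[hold] <- predict_meta(m, profile[hold, ])
  }
  expect_equal(
    pseustack:::meta_cv_accuracy(profile, y, rep(1, 30), folds),
    mean((pred >= 0.5) == y)
  )

  # end-to-end seeded determinism
  res2 <- optimize_weights(profile, y, config = cfg, seed = 17)
  expect_identical(res$w, res2$w)
  expect_identical(res$history, res2$history)
})

test_that("degenerate labels are rejected", {
  profile <- matrix(runif(40), 20, 2)
  expect_error(optimize_weights(profile, rep(1L, 20)), "both classes")
})
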