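#' Initialize a particle swarm
#'
#' Positions are drawn uniformly on `[0,1]^D`, velocities uniformly on
#' `[-vmax, vmax]`; every particle's personal best starts at its initial
#' position and the global best is the fittest initial particle.
#'
#' @param config A [pso_config()].
#' @param D Search-space dimension (the profile width).
#' @param fitness_fn Function mapping a weight vector to a scalar
#'   fitness (higher is better).
#' @param seed Integer seed, or `NULL` to consume the current RNG
#'   stream.
#' @return A `pseu_pso_state` list with positions `x`, velocities `v`,
#'   `pbest`/`pbest_fit`, `gbest`/`gbest_fit`, iteration counter `t` and
#'   an empty `history`.
#' @export
init_swarm <- function(config, D, fitness_fn, seed = NULL) {
  stopifnot(D >= 1)
  if (!is.null(seed)) set.seed(seed)
  np <- config$n_particles
  x <- matrix(runif(np * D), np, D)
  v <- matrix(runif(np * D, -config$vmax, config$vmax), np, D)
  fit <- eval_swarm(x, fitness_fn)
  g <- which.max(fit)
  structure(
    list(x = x, v = v, fitness = fit,
         pbest = x, pbest_fit = fit,
         gbest = x[g, ], gbest_fit = fit[g],
         t = 0L, history = numeric(0), config = config),
    class = "pseu_pso_state"
  )
}

eval_swarm <- function(x, fitness_fn) {
  vapply(seq_len(nrow(x)), function(i) {
    tryCatch(fitness_fn(x[i, ]),
             error = function(e) abort(paste0(
               "Fitness evaluation failed for particle ", i, ": ",
               conditionMessage(e))))
  }, numeric(1))
}

#' One particle-swarm iteration
#'
#' Standard inertia-weight update: each particle's velocity becomes
#' `w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with fresh uniform
#' `r1, r2` per particle and dimension, clamped to `[-vmax, vmax]`; the
#' new position is `x + v`, clipped to the `[0,1]` box (absorbing
#' walls). Personal and global bests are updated wherever fitness
#' strictly improves, so the global-best fitness never decreases.
#'
#' @param state A `pseu_pso_state`.
#' @param fitness_fn Fitness function (see [init_swarm()]).
#' @param config Swarm settings; defaults to those stored in `state`.
#' @return The updated `pseu_pso_state` (iteration counter advanced,
#'   `history` appended with the current global-best fitness).
#' @export
pso_step <- function(state, fitness_fn, config = state$config) {
  np <- nrow(state$x); D <- ncol(state$x)
  r1 <- matrix(runif(np * D), np, D)
  r2 <- matrix(runif(np * D), np, D)
  v <- config$inertia * state$v +
    config$c1 * r1 * (state$pbest - state$x) +
    config$c2 * r2 * (matrix(state$gbest, np, D, byrow = TRUE) - state$x)
  v <- pmin(pmax(v, -config$vmax), config$vmax)
  x <- pmin(pmax(state$x + v, 0), 1)
  fit <- eval_swarm(x, fitness_fn)

  improved <- fit > state$pbest_fit
  state$pbest[improved, ] <- x[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fit[improved]
  g <- which.max(state$pbest_fit)
  if (state$pbest_fit[g] > state$gbest_fit) {
    state$gbest <- state$pbest[g, ]
    state$gbest_fit <- state$pbest_fit[g]
  }
  state$x <- x
  state$v <- v
  state$fitness <- fit
  state$t <- state$t + 1L
  state$history <- c(state$history, state$gbest_fit)
  state
}

#' Search profile weights by particle swarm
#'
#' Runs the swarm over the `[0,1]^D` weight box. The fitness of a weight
#' vector `w` is the stratified `fitness_folds`-fold cross-validated
#' accuracy of the logistic meta-classifier trained on the column-wise
#' weighted profile `profile * w`. The CV partition is drawn once per
#' call and shared by every particle and iteration, making fitness a
#' deterministic function of `w` (and global-best monotonicity
#' well-defined).
#'
#' @param profile RNA profile matrix (rows = sequences).
#' @param labels Binary labels for its rows.
#' @param config A [pso_config()].
#' @param seed Integer seed covering the CV partition and all swarm
#'   randomness.
#' @param meta_lambda Ridge penalty of the meta-classifier (`NULL` =
#'   `1/n`).
#' @return A `pseu_weights` object: `w` (the global-best weights),
#'   `fitness` (its CV accuracy), `history` (global-best fitness after
#'   each iteration, non-decreasing, length `n_iterations`),
#'   `initial_fitness` (global best of the initial swarm), plus column
#'   metadata when the profile carries it.
#' @export
optimize_weights <- function(profile, labels, config = pso_config(),
                             seed = 1L, meta_lambda = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("optimize_weights: both classes must be present.")
  }
  D <- ncol(profile)
  set.seed(seed)
  folds <- stratified_folds(labels, config$fitness_folds, seed = seed)
  fitness_fn <- function(w) {
    meta_cv_accuracy(profile, labels, w, folds, meta_lambda)
  }
  state <- init_swarm(config, D, fitness_fn, seed = NULL)
  initial_fitness <- state$gbest_fit
  for (t in seq_len(config$n_iterations)) {
    state <- pso_step(state, fitness_fn)
  }
  structure(
    list(w = state$gbest, fitness = state$gbest_fit,
         history = state$history, initial_fitness = initial_fitness,
         columns = attr(profile, "columns"), config = config, seed = seed),
    class = "pseu_weights"
  )
}

#' @export
print.pseu_weights <- function(x, ...) {
  cat(sprintf(
    "<pseu_weights> D = %d, CV-accuracy fitness %.4f (from %.4f at init, %d iterations)\n",
    length(x$w), x$fitness, x$initial_fitness, length(x$history)
  ))
  invisible(x)
}
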