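# Fixtures are generated in code: uridine-centered windows with or
# without class signal, and reduced configurations that keep the full
# architecture but shrink its cost.

# random uridine-centered windows, uniform background, no class signal
random_windows <- function(n, lambda = 9, seed = 1, labeled = TRUE) {
  spec <- synthetic_spec(window_length = lambda, n_pos = ceiling(n / 2),
                         n_neg = floor(n / 2), seed = seed)
  w <- generate_windows(spec)
  if (!labeled) w$label <- NA_integer_
  rna_windows(w)
}

# strongly separable windows via the human-like preset
separable_windows <- function(n = 60, seed = 1, strength = 0.9) {
  generate_windows(preset_spec("human_like", n_pos = ceiling(n / 2),
                               n_neg = floor(n / 2),
                               strength = strength, seed = seed))
}

# tiny but architecturally complete configuration for integration tests
tiny_config <- function(seed = 1, ...) {
  fast_config(
    seed = seed,
    pso = pso_config(n_particles = 6, n_iterations = 4, fitness_folds = 3),
    stacking_folds = 3,
    fs = list(n_folds = 2, max_thresholds = 3),
    ...
  )
}

# reduced feature matrix fixture: labeled rows, one informative feature
informative_matrix <- function(n = 60, p = 6, seed = 1, flip = 0.05) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  noisy <- rbinom(n, 1, flip) == 1
  X[, 1] <- ifelse(noisy, 1L - y, y)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}
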