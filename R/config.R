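#' Particle swarm settings
#'
#' Defaults follow the published search configuration for this
#' architecture: 60 particles, 100 iterations, inertia 0.8, personal and
#' social learning factors both 0.6, positions (= profile weights)
#' constrained to `[0, 1]`, and 10-fold cross-validated meta-classifier
#' accuracy as the fitness. The velocity clamp `vmax` (fraction of the
#' unit box, default 0.2) is an implementation choice that keeps
#' particles from bouncing between the walls.
#'
#' @param n_particles Swarm size.
#' @param n_iterations Number of update sweeps.
#' @param inertia Inertia weight `w` on the previous velocity.
#' @param c1,c2 Personal and social learning factors.
#' @param vmax Velocity clamp, in units of the `[0,1]` position range.
#' @param fitness_folds Folds for the CV-accuracy fitness.
#' @return A `pso_config` list.
#' @export
pso_config <- function(n_particles = 60, n_iterations = 100, inertia = 0.8,
                       c1 = 0.6, c2 = 0.6, vmax = 0.2, fitness_folds = 10) {
  stopifnot(n_particles >= 1, n_iterations >= 1, vmax > 0, fitness_folds >= 2)
  structure(
    list(n_particles = n_particles, n_iterations = n_iterations,
         inertia = inertia, c1 = c1, c2 = c2, vmax = vmax,
         fitness_folds = fitness_folds),
    class = "pso_config"
  )
}

#' Full pipeline configuration
#'
#' Gathers every knob of the predictor in one list: the encodings, the
#' base-classifier families and their hyperparameters, the
#' feature-selection sweep settings, the stacking fold count, the PSO
#' settings, the meta-classifier ridge penalty, and the master seed.
#' The defaults reproduce the full architecture: 6 encodings x 5
#' families = 30 profile columns, 10 stacking folds, a 60-particle /
#' 100-iteration swarm with 10-fold fitness.
#'
#' @param encodings Tibble from [encoding_specs()] (subset to shrink the
#'   profile).
#' @param families Character vector of base families in registry order.
#' @param base_params Per-family hyperparameter overrides (see
#'   [base_registry()]).
#' @param fs Feature-selection settings: `n_folds`, `max_thresholds`,
#'   `metric`.
#' @param stacking_folds Folds for the out-of-fold profile (default 10).
#' @param pso A [pso_config()].
#' @param meta_lambda Ridge penalty of the logistic meta-classifier;
#'   `NULL` means `1/n` (unit-strength L2, the common default).
#' @param seed Master seed; every stage derives its seed from it.
#' @return A `pseu_config` list.
#' @export
pseu_config <- function(encodings = encoding_specs(),
                        families = base_registry()$family,
                        base_params = list(),
                        fs = list(),
                        stacking_folds = 10,
                        pso = pso_config(),
                        meta_lambda = NULL,
                        seed = 1L) {
  fs <- modifyList(list(n_folds = 5, max_thresholds = 200,
                        metric = "accuracy"), fs)
  structure(
    list(encodings = encodings, families = families,
         base_params = base_params, fs = fs,
         stacking_folds = stacking_folds, pso = pso,
         meta_lambda = meta_lambda, seed = as.integer(seed)),
    class = "pseu_config"
  )
}

#' Fast configuration profile
#'
#' A reduced-cost configuration for continuous testing and interactive
#' work: the same 30-column architecture, but a 10-particle /
#' 20-iteration swarm with 5-fold fitness, 5 stacking folds, a 6-point
#' 3-fold feature-selection sweep, and lighter boosted ensembles
#' (15 AdaBoost rounds, 30 boosting rounds). Use the default
#' [pseu_config()] for production-scale runs.
#'
#' @param seed Master seed.
#' @param ... Further overrides passed to [pseu_config()].
#' @return A `pseu_config` list.
#' @export
fast_config <- function(seed = 1L, ...) {
  defaults <- list(
    base_params = list(
      ADA = list(n_rounds = 15),
      GBDT = list(nrounds = 30),
      XGB = list(nrounds = 30)
    ),
    fs = list(n_folds = 3, max_thresholds = 6),
    stacking_folds = 5,
    pso = pso_config(n_particles = 10, n_iterations = 20, fitness_folds = 5),
    seed = seed
  )
  do.call(pseu_config, modifyList(defaults, list(...)))
}
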