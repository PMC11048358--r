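small_cfg <- function(seed = 3) {
  tiny_config(
    seed = seed,
    encodings = encoding_specs()[c(1, 2, 4), ],  # onehot1, onehot2, kmer1
    families = c("ADA", "XGB", "RF"),
    base_params = list(ADA = list(n_rounds = 8), XGB = list(nrounds = 15),
                       RF = list(num.trees = 25))
  )
}

test_that("the fitted predictor separates a strong synthetic motif", {
  w <- separable_windows(80, seed = 1)
  m <- fit_pseu(w, small_cfg())
  expect_s3_class(m, "pseu_model")
  expect_equal(ncol(m$profile), 9)
  pred <- predict(m, w)
  expect_equal(pred$id, w$id)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_gt(mean(pred$label == w$label), 0.9)

  # duplicated input gets identical probabilities
  dup <- rna_windows(dplyr::bind_rows(tibble::as_tibble(w)[1, ],
                                      tibble::as_tibble(w)[1, ]) |>
                       dplyr::mutate(id = c("d1", "d2")))
  pd <- predict(m, dup)
  expect_equal(pd$probability[1], pd$probability[2])
})

test_that("refitting with the same config and seed is bit-identical", {
  w <- separable_windows(50, seed = 2)
  m1 <- fit_pseu(w, small_cfg(seed = 7))
  m2 <- fit_pseu(w, small_cfg(seed = 7))
  expect_identical(m1$weights$w, m2$weights$w)
  expect_identical(meta_coefficients(m1$meta), meta_coefficients(m2$meta))
  expect_identical(predict(m1, w), predict(m2, w))
})

test_that("the pipeline equals stage-by-stage manual execution", {
  w <- separable_windows(40, seed = 5)
  cfg <- small_cfg(seed = 11)
  m <- fit_pseu(w, cfg)

  feats <- pseustack:::encode_all(w, cfg$encodings)
  masks <- select_features(w, cfg, features = feats)
  prof <- oof_profile(w, masks = masks, config = cfg, features = feats)
  wts <- optimize_weights(prof$profile, w$label, config = cfg$pso,
                          seed = cfg$seed, meta_lambda = cfg$meta_lambda)
  meta <- fit_meta(sweep(prof$profile, 2, wts$w, "*"), w$label,
                   lambda = cfg$meta_lambda)

  expect_identical(m$weights$w, wts$w)
  expect_equal(unname(m$profile), unname(prof$profile))
  expect_identical(meta_coefficients(m$meta), meta_coefficients(meta))
})

test_that("model bundles round-trip through save/load", {
  w <- separable_windows(40, seed = 6)
  m <- fit_pseu(w, small_cfg(), run_pso = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_pseu(m, path)
  m2 <- load_pseu(path)
  expect_identical(predict(m, w), predict(m2, w))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_pseu(bad), "Not a pseu_model")
})

test_that("prediction rejects mismatched window lengths with ids intact", {
  w <- separable_windows(40, seed = 6)
  m <- fit_pseu(w, small_cfg(), run_pso = FALSE)
  wrong <- random_windows(3, lambda = 11)
  expect_error(predict(m, wrong), "length mismatch")
})

test_that("skipping the weight search leaves unit weights", {
  w <- separable_windows(40, seed = 8)
  m <- fit_pseu(w, small_cfg(), run_pso = FALSE)
  expect_equal(m$weights$w, rep(1, 9))
  expect_length(m$weights$history, 0)
  # weighted and unweighted meta coincide at w = 1
  expect_equal(meta_coefficients(m$meta),
               meta_coefficients(m$meta_unweighted))
})

test_that("tidy and glance summarize the fitted ensemble", {
  w <- separable_windows(40, seed = 9)
  m <- fit_pseu(w, small_cfg())
  td <- tidy(m)
  expect_equal(nrow(td), 9)
  expect_true(all(c("column", "weight", "coefficient", "n_features_kept",
                    "oof_mcc") %in% names(td)))
  expect_true(all(td$weight >= 0 & td$weight <= 1))
  gl <- glance(m)
  expect_equal(gl$n_train, 40)
  expect_equal(gl$n_profile_columns, 9)
  expect_equal(gl$window_length, 21)
})

test_that("stage failures are tagged with the failing stage", {
  # a lone positive makes one selection-CV training split single-class
  w <- generate_windows(synthetic_spec(window_length = 21, n_pos = 1,
                                       n_neg = 11, seed = 10))
  expect_error(fit_pseu(w, small_cfg()), "fit_pseu \\[feature_selection\\]")
})
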