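# a reduced architecture (2 encodings x 2 families) keeps these tests
# quick; the full 30-column layout is exercised in the acceptance suite
mini_config <- function(seed = 1) {
  tiny_config(
    seed = seed,
    encodings = encoding_specs()[c(1, 4), ],  # onehot1, kmer1
    families = c("ADA", "RF"),
    base_params = list(ADA = list(n_rounds = 8), RF = list(num.trees = 25))
  )
}

test_that("profile columns are encoding-major with registry family order", {
  cols <- profile_columns()
  expect_equal(nrow(cols), 30)
  expect_equal(cols$column[1:5],
               paste0("onehot1_", c("ADA", "GBDT", "XGB", "RF", "ET")))
  expect_equal(cols$column[26:30],
               paste0("kmer3_", c("ADA", "GBDT", "XGB", "RF", "ET")))
})

test_that("the out-of-fold profile has the right shape and probability entries", {
  w <- separable_windows(36, seed = 2)
  cfg <- mini_config()
  prof <- oof_profile(w, masks = NULL, config = cfg)
  expect_equal(dim(prof$profile), c(36, 4))
  expect_equal(colnames(prof$profile),
               c("onehot1_ADA", "onehot1_RF", "kmer1_ADA", "kmer1_RF"))
  expect_true(all(prof$profile >= 0 & prof$profile <= 1))
  expect_equal(attr(prof$profile, "provenance"), "out_of_fold")
  expect_equal(sort(unique(prof$fold_models$folds)), 1:3)
})

test_that("profile entries match a brute-force out-of-fold refit", {
  w <- separable_windows(24, seed = 3)
  cfg <- mini_config(seed = 5)
  prof <- oof_profile(w, masks = NULL, config = cfg)
  fm <- prof$fold_models
  y <- w$label
  reg <- base_registry(cfg$base_params)
  for (i in seq_len(nrow(fm$columns))) {
    enc <- fm$columns[i, ]
    X <- encode_windows(w, enc$scheme, enc$k)
    for (f in sort(unique(fm$folds))) {
      hold <- fm$folds == f
      m <- fit_base(enc$family, X[!hold, , drop = FALSE], y[!hold],
                    params = reg$params[[match(enc$family, reg$family)]],
                    seed = cfg$seed + i)
      expect_equal(unname(prof$profile[hold, i]),
                   predict_base(m, X[hold, , drop = FALSE]),
                   tolerance = 1e-12)
    }
  }
})

test_that("test profiles average the fold models' probabilities", {
  w <- separable_windows(30, seed = 6)
  new <- separable_windows(10, seed = 7)
  cfg <- mini_config()
  prof <- oof_profile(w, masks = NULL, config = cfg)
  tp <- test_profile(prof$fold_models, new)
  expect_equal(attr(tp, "provenance"), "averaged_test")
  expect_true(all(tp >= 0 & tp <= 1))

  # manual average for one column
  i <- 2
  enc <- prof$fold_models$columns[i, ]
  X <- encode_windows(new, enc$scheme, enc$k)
  per_fold <- sapply(prof$fold_models$models[[i]],
                     function(m) predict_base(m, X))
  expect_equal(unname(tp[, i]), unname(rowMeans(per_fold)), tolerance = 1e-12)

  # window-length mismatch is an argument error
  wrong <- random_windows(4, lambda = 11)
  expect_error(test_profile(prof$fold_models, wrong), "length mismatch")
})

test_that("averaging hand-listed fold probabilities gives their mean", {
  # mean of (0.1, 0.2, 0.3, 0.4, 0.5) = 0.3, the k-fold averaging rule
  expect_equal(mean(c(0.1, 0.2, 0.3, 0.4, 0.5)), 0.3)
})

test_that("per-column MCC flags perfect, inverted and random columns", {
  set.seed(8)
  y <- rep(c(0L, 1L), each = 250)
  profile <- cbind(
    perfect = y * 0.8 + 0.1,
    inverted = (1 - y) * 0.8 + 0.1,
    noise = runif(500)
  )
  mcc <- profile_column_mcc(profile, y)
  expect_equal(mcc$mcc[mcc$column == "perfect"], 1)
  expect_equal(mcc$mcc[mcc$column == "inverted"], -1)
  expect_lt(abs(mcc$mcc[mcc$column == "noise"]), 0.15)
})

test_that("stacking refuses folds that would lose a class", {
  w <- generate_windows(synthetic_spec(window_length = 9, n_pos = 1,
                                       n_neg = 11, seed = 9))
  cfg <- mini_config()
  cfg$stacking_folds <- 2
  # the lone positive sits in one fold, so the other training part
  # loses the class entirely
  expect_error(oof_profile(w, masks = NULL, config = cfg),
               "lost one class")
})
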