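test_that("presets validate with benchmark window lengths", {
  specs <- default_specs()
  expect_named(specs, c("human_like", "yeast_like"))
  expect_equal(specs$human_like$window_length, 21L)
  expect_equal(specs$yeast_like$window_length, 31L)
  expect_s3_class(specs$human_like, "synthetic_spec")
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_spec(window_length = 20), "odd")
  expect_error(
    synthetic_spec(enrichment = list("1" = list(pos = c(1, 1, 0, 0),
                                                neg = rep(0.25, 4)))),
    "summing to 1"
  )
  expect_error(
    synthetic_spec(window_length = 9,
                   enrichment = list("0" = list(pos = rep(0.25, 4),
                                                neg = rep(0.25, 4)))),
    "offset"
  )
  expect_error(
    synthetic_spec(window_length = 9,
                   enrichment = list("8" = list(pos = rep(0.25, 4),
                                                neg = rep(0.25, 4)))),
    "within"
  )
})

test_that("every generated window is uridine-centered and seed-stable", {
  spec <- preset_spec("yeast_like", n_pos = 40, n_neg = 40, seed = 5)
  w <- generate_windows(spec)
  expect_equal(nrow(w), 80)
  expect_equal(window_length(w), 31L)
  expect_true(all(substr(w$sequence, 16, 16) == "U"))
  expect_equal(w$label, rep(c(1L, 0L), each = 40))
  expect_identical(as.data.frame(generate_windows(spec)), as.data.frame(w))
  spec2 <- preset_spec("yeast_like", n_pos = 40, n_neg = 40, seed = 6)
  expect_false(identical(generate_windows(spec2)$sequence, w$sequence))
})

test_that("empirical composition at an enriched offset matches the spec", {
  spec <- preset_spec("human_like", n_pos = 1000, n_neg = 1000,
                      strength = 1, seed = 11)
  w <- generate_windows(spec)
  plus1 <- substr(w$sequence, 12, 12)  # offset +1 from the center (pos 11)
  for (cls in c(1, 0)) {
    freq <- table(factor(plus1[w$label == cls], levels = c("A", "C", "G", "U")))
    freq <- as.vector(freq) / sum(w$label == cls)
    want <- spec$enrichment[["+1"]][[if (cls == 1) "pos" else "neg"]]
    expect_true(all(abs(freq - want) < 0.03))
  }
})

test_that("unenriched positions follow the background composition", {
  spec <- preset_spec("human_like", n_pos = 1000, n_neg = 1000, seed = 13)
  w <- generate_windows(spec)
  pos3 <- substr(w$sequence, 3, 3)  # offset -8: background
  freq <- as.vector(table(factor(pos3, levels = c("A", "C", "G", "U")))) / 2000
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("markov stickiness induces dinucleotide repetition", {
  base <- synthetic_spec(window_length = 21, n_pos = 400, n_neg = 0, seed = 3)
  sticky <- synthetic_spec(window_length = 21, n_pos = 400, n_neg = 0,
                           markov_stickiness = c(pos = 0.5, neg = 0),
                           seed = 3)
  rep_rate <- function(w) {
    s <- w$sequence
    mean(vapply(s, function(x) {
      ch <- strsplit(x, "")[[1]]
      mean(ch[-1] == ch[-length(ch)])
    }, numeric(1)))
  }
  expect_gt(rep_rate(generate_windows(sticky)),
            rep_rate(generate_windows(base)) + 0.2)
})

test_that("motif strength moves the learned separation (recovery dial)", {
  cfg <- tiny_config(
    seed = 4,
    encodings = encoding_specs()[c(1, 4), ],
    families = c("ADA", "RF"),
    base_params = list(ADA = list(n_rounds = 8), RF = list(num.trees = 25))
  )
  acc_at <- function(strength) {
    w <- generate_windows(preset_spec("human_like", n_pos = 50, n_neg = 50,
                                      strength = strength, seed = 8))
    prof <- oof_profile(w, masks = NULL, config = cfg)
    folds <- stratified_folds(w$label, 5, seed = 4)
    pseustack:::meta_cv_accuracy(prof$profile, w$label, rep(1, 4), folds)
  }
  expect_gt(acc_at(0.9), acc_at(0.1) + 0.1)
})
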