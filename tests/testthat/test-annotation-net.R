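ns <- asNamespace("shemon")

test_that("model maps a 2000-sample window to a (2000, 9) score field", {
  cfg <- seq2seq_config()           # full-size default: 9 classes
  m <- build_seq2seq(cfg)
  probs <- predict_seq2seq(m, rnorm(2000))
  expect_identical(dim(probs), c(2000L, 9L, 1L))
  sums <- apply(probs, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("architecture is length-parametric", {
  cfg <- seq2seq_config(seq_len = 1000, stem_filters = 4, n_blocks = 2,
                        branch_filters = 3, decoder_filters = 4)
  m <- build_seq2seq(cfg)
  probs <- predict_seq2seq(m, rnorm(1000))
  expect_identical(dim(probs), c(1000L, 9L, 1L))
  expect_error(seq2seq_config(seq_len = 1001), "divisible")
  expect_error(predict_seq2seq(m, rnorm(999)), "length")
})

test_that("a tiny model memorizes a small window set", {
  ds <- make_training_set(60, c(background = .5, VEB = .5), seed = 15,
                          class_scheme = c(background = 0L, VEB = 1L))
  cfg <- seq2seq_config(n_classes = 2, stem_filters = 8, n_blocks = 2,
                        branch_filters = 6, decoder_filters = 12,
                        activation = "relu", lr0 = 0.003, epochs = 16,
                        batch_size = 8, val_frac = 0.1,
                        class_weighting = FALSE, seed = 5)
  m <- train_seq2seq(ds, cfg)
  expect_gte(max(tail(m$history$train_acc, 3)), 0.95)
  # validation loss decreases overall and is non-increasing within a small
  # slack for minibatch jitter
  vl <- m$history$val_loss
  expect_lt(tail(vl, 1), 0.5 * vl[1])
  expect_true(all(diff(vl) < 1e-3 + 0.1 * head(vl, -1)))
})

test_that("training is deterministic given the seed", {
  ds <- make_training_set(24, c(background = .5, VEB = .5), seed = 16,
                          class_scheme = scheme4)
  cfg <- seq2seq_config(n_classes = 4, stem_filters = 4, n_blocks = 2,
                        branch_filters = 3, decoder_filters = 4,
                        activation = "relu", epochs = 2, batch_size = 8,
                        seed = 11)
  m1 <- suppressWarnings(train_seq2seq(ds, cfg))  # absent-class warning
  m2 <- suppressWarnings(train_seq2seq(ds, cfg))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("learning rate drops by the configured factor on a plateau", {
  # constant labels saturate validation accuracy immediately, forcing the
  # plateau rule: after `patience` non-improving epochs, lr is divided by 10
  ds <- make_training_set(24, c(background = 1), seed = 17,
                          class_scheme = scheme4)
  cfg <- suppressWarnings(
    seq2seq_config(n_classes = 4, stem_filters = 4, n_blocks = 2,
                   branch_filters = 3, decoder_filters = 4,
                   activation = "relu", lr0 = 0.01, epochs = 30,
                   batch_size = 8, patience = 2, seed = 11))
  m <- suppressWarnings(train_seq2seq(ds, cfg))
  h <- m$history
  expect_identical(h$lr[1], 0.01)           # starts at lr0
  expect_true(all(diff(h$lr) <= 0))          # never rises
  expect_lt(tail(h$lr, 1), 0.01)            # a plateau drop occurred
  steps <- unique(h$lr)
  expect_equal(head(steps, -1) / steps[-1], rep(10, length(steps) - 1))
  # the first drop lands `patience` epochs after accuracy saturates
  sat <- which(h$val_acc >= max(h$val_acc))[1]
  first_drop <- which(h$lr < h$lr[1])[1]
  expect_gte(first_drop, sat + cfg$patience)
})

test_that("beat voting picks the majority class, ties by mean probability", {
  # construct a probability field directly
  flat <- matrix(0.1, nrow = 100, ncol = 3)
  cls <- rep(0L, 100)
  cls[41:60] <- 1L                  # 20 votes for class 1 in [40, 60]
  v <- ns$vote_beat_class(flat, cls, 40L, 60L)
  expect_identical(v$class, 1L)
  expect_equal(v$confidence, 20 / 21)
  # exact tie between classes 1 and 2: 10 votes each; mean prob decides
  cls2 <- c(rep(1L, 10), rep(2L, 10))
  flat2 <- matrix(0.2, nrow = 20, ncol = 3)
  flat2[, 3] <- 0.5                 # class 2 has higher mean probability
  v2 <- ns$vote_beat_class(flat2, cls2, 0L, 19L)
  expect_identical(v2$class, 2L)
  flat2[, 2] <- 0.9                 # now class 1 wins the tie
  v3 <- ns$vote_beat_class(flat2, cls2, 0L, 19L)
  expect_identical(v3$class, 1L)
})

test_that("annotation flags ectopic beats on a synthetic record", {
  m <- tiny_veb_model()
  rec <- synth_ecg(ecg_synth_config(ectopic = c(VEB = 15), duration_s = 32,
                                    seed = 19))
  res <- annotate(m, rec)
  expect_s3_class(res$beat_annotations, "data.frame")
  truth <- rec$beat_labels
  veb_idx <- truth$index[truth$cls == "V"]
  ann_veb <- res$beat_annotations$index[res$beat_annotations$class_name == "VEB"]
  # at least one true ventricular ectopic is annotated as such, and flagged
  expect_gt(length(intersect_within(ann_veb, veb_idx, 15)), 0)
  expect_true("abnormal_beat" %in% res$flags)

  # a normal record through the same model raises no ectopic flag
  rec0 <- synth_ecg(ecg_synth_config(duration_s = 32, seed = 20))
  res0 <- annotate(m, rec0)
  expect_false("abnormal_beat" %in% res0$flags)
})

test_that("checkpoints round-trip through save_model/load_model", {
  cfg <- seq2seq_config(seq_len = 96, n_classes = 3, stem_filters = 3,
                        n_blocks = 2, branch_filters = 2, decoder_filters = 3,
                        seed = 2)
  m <- build_seq2seq(cfg, class_names = c("a", "b", "c"))
  dir <- file.path(withr::local_tempdir(), "ckpt")
  save_model(m, dir)
  back <- load_model(dir)
  x <- rnorm(96)
  expect_equal(predict_seq2seq(back, x), predict_seq2seq(m, x),
               tolerance = 1e-12)
  expect_identical(back$class_names, c("a", "b", "c"))
})
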