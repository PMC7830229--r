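quick_cv_args <- list(window = c(8, 4), hidden = c(5, 5), batch_size = 10,
                      epochs = 3, pretrain = FALSE, seed = 1)

test_that("cross-validation bookkeeping: k folds, consistent summaries", {
  rec <- generate_series(synth_spec(n_channels = 2, n_samples = 5000,
                                    mean_dwell = 200, seed = 2))
  cv <- do.call(crossval, c(list(record = rec, k = 10, ts = 1), quick_cv_args))
  expect_length(cv$per_fold, 10L)
  expect_true(all(cv$per_fold >= 0 & cv$per_fold <= 100))
  expect_equal(cv$mean, mean(cv$per_fold))
  expect_equal(cv$sd, sd(cv$per_fold))
})

test_that("cross-validation is reproducible from the seed", {
  rec <- generate_series(synth_spec(n_channels = 2, n_samples = 3000,
                                    mean_dwell = 200, seed = 3))
  cv1 <- do.call(crossval, c(list(record = rec, k = 3, ts = 2), quick_cv_args))
  cv2 <- do.call(crossval, c(list(record = rec, k = 3, ts = 2), quick_cv_args))
  expect_identical(cv1$per_fold, cv2$per_fold)
})

test_that("fold results do not depend on execution order", {
  rec <- generate_series(synth_spec(n_channels = 2, n_samples = 3000,
                                    mean_dwell = 200, seed = 4))
  cv <- do.call(crossval, c(list(record = rec, k = 3, ts = 1), quick_cv_args))
  ## recompute the folds in reverse order through the internal runner
  ws <- sliding_window(rec, window_spec(8, 4))
  batches <- make_minibatches(ws, 10, 5)
  nb <- length(batches)
  fold_id <- rep(1:3, times = diff(round(seq(0, nb, length.out = 4))))
  cfg <- cv$config
  reversed <- vapply(3:1, function(f) {
    dtcn:::run_fold(batches[fold_id != f], batches[fold_id == f], cfg,
                    seed = dtcn:::derive_seed(1, 1000 + f))
  }, numeric(1))
  expect_equal(rev(reversed), cv$per_fold)
})

test_that("no test-fold information reaches training", {
  rec <- generate_series(synth_spec(n_channels = 2, n_samples = 3000,
                                    mean_dwell = 200, seed = 5))
  ws <- sliding_window(rec, window_spec(8, 4))
  batches <- make_minibatches(ws, 10, 5)
  train <- batches[1:15]; test <- batches[16:20]
  poisoned <- lapply(test, function(b) { b$features <- b$features + 1e6; b })
  cfg <- list(hidden = c(5, 5), ts = 2, epochs = 3, lr = 0.05, momentum = 0.9,
              pretrain = TRUE, pretrain_epochs = 2, pretrain_lr = 0.05,
              cd_k = 1, soft_targets = FALSE,
              n_input = ncol(ws$features), n_classes = 2)
  clean <- dtcn:::run_fold(train, test, cfg, seed = 7, return_fit = TRUE)
  dirty <- dtcn:::run_fold(train, poisoned, cfg, seed = 7, return_fit = TRUE)
  expect_identical(clean$params, dirty$params)   # training untouched
  expect_identical(clean$center, dirty$center)   # statistics from train only
  expect_identical(clean$scale, dirty$scale)
})

test_that("the TS sweep reports parameter counts and matched baselines", {
  rec <- generate_series(synth_spec(n_channels = 14, n_samples = 4000,
                                    mean_dwell = 200, seed = 6))
  sw <- ts_sweep(rec, ts_values = c(1, 2), include_equivalent = TRUE,
                 window = c(16, 8), hidden = c(20, 20, 20), batch_size = 10,
                 k = 3, epochs = 2, pretrain = FALSE, seed = 1)
  expect_s3_class(sw, "dtcn_sweep")
  expect_equal(nrow(sw), 3L)
  expect_true(all(c("model", "ts", "param_count", "mean", "sd") %in% names(sw)))
  ## 14 channels x window 16 gives the 224-input configuration whose
  ## TS = 2 complexity match widens the hidden layers to 23, 23, 20
  eq <- sw[sw$model == "equivalent", ]
  expect_equal(eq$hidden, "23-23-20")
  expect_equal(eq$param_count, 6181)
  expect_equal(sw$param_count[sw$model == "dtcn" & sw$ts == 2], 6160)
  ## a single-value sweep row reproduces a plain crossval run
  sw1 <- ts_sweep(rec, ts_values = 1, include_equivalent = FALSE,
                  window = c(16, 8), hidden = c(20, 20, 20), batch_size = 10,
                  k = 3, epochs = 2, pretrain = FALSE, seed = 1)
  cv1 <- crossval(rec, k = 3, ts = 1, window = c(16, 8),
                  hidden = c(20, 20, 20), batch_size = 10, epochs = 2,
                  pretrain = FALSE, seed = 1)
  expect_equal(sw1$mean, cv1$mean)
})
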