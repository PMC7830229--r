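test_that("window overlap percentage follows (w - s)/w * 100", {
  expect_equal(compute_overlap(window_spec(128, 64)), 50)
  expect_equal(compute_overlap(window_spec(16, 16)), 0)
  expect_equal(compute_overlap(window_spec(4, 1)), 75)
  expect_error(window_spec(0, 1), "invalid window spec")
  expect_error(window_spec(4, 5), "invalid window spec")
})

test_that("sliding window emits floor((N - w)/s) + 1 vectors at the right offsets", {
  rec <- ts_record(matrix(seq_len(20), 10, 2), rep(0L, 10), n_classes = 2)
  ws <- sliding_window(rec, window_spec(4, 2))
  expect_equal(nrow(ws$features), 4L)
  expect_equal(ws$t_index, c(0L, 2L, 4L, 6L))
  ## channel-major layout: all w lags of channel 1 first
  expect_equal(ws$features[1, ], c(1:4, 11:14))
  expect_equal(ws$features[3, ], c(5:8, 15:18))
})

test_that("feature width is w times the channel count", {
  rec14 <- ts_record(matrix(rnorm(14 * 40), 40, 14), rep(0L, 40), n_classes = 2)
  expect_equal(ncol(sliding_window(rec14, window_spec(16, 8))$features), 224L)
  rec6 <- ts_record(matrix(rnorm(6 * 150), 150, 6), rep(0L, 150), n_classes = 2)
  expect_equal(ncol(sliding_window(rec6, window_spec(128, 64))$features), 768L)
})

test_that("windowing refuses series shorter than one window", {
  rec <- ts_record(matrix(rnorm(6), 3, 2), rep(0L, 3), n_classes = 2)
  expect_error(sliding_window(rec, window_spec(4, 2)), "too short")
})

test_that("per-window label counts tally samples and cover the series", {
  set.seed(5)
  N <- 48L
  labels <- sample(0:2, N, replace = TRUE)
  rec <- ts_record(matrix(rnorm(N), N, 1), labels, n_classes = 3)
  ws <- sliding_window(rec, window_spec(8, 8))   # non-overlapping
  expect_true(all(rowSums(ws$label_counts) == 8L))
  ## concatenated counts over s = w windows reproduce the global histogram
  expect_equal(colSums(ws$label_counts),
               tabulate(labels + 1L, nbins = 3L),
               ignore_attr = TRUE)
  ## every window lies inside [0, N)
  expect_true(all(ws$t_index >= 0 & ws$t_index + 8 <= N))
})

test_that("second-stage windowing forms overlapping mini-batches in time order", {
  rec <- ts_record(matrix(rnorm(100), 50, 2), rep(0L, 50), n_classes = 2)
  ws <- sliding_window(rec, window_spec(4, 2))   # 24 vectors
  expect_equal(length(make_minibatches(ws, 8, 4)), 5L)

  ## spec arithmetic on exactly V = 20 vectors
  ws20 <- sliding_window(ts_record(matrix(rnorm(84), 42, 2), rep(0L, 42),
                                   n_classes = 2), window_spec(4, 2))
  expect_equal(nrow(ws20$features), 20L)
  expect_equal(length(make_minibatches(ws20, 8, 4)), 4L)

  ## single batch covering all vectors
  ws18 <- sliding_window(ts_record(matrix(rnorm(76), 38, 2), rep(0L, 38),
                                   n_classes = 2), window_spec(4, 2))
  one <- make_minibatches(ws18, 18, 1)
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$features), 18L)

  expect_error(make_minibatches(ws18, 40), "too few")
})

test_that("batch_stride = B gives disjoint batches covering a prefix once", {
  rec <- ts_record(matrix(rnorm(100), 50, 2), rep(0L, 50), n_classes = 2)
  ws <- sliding_window(rec, window_spec(4, 2))
  batches <- make_minibatches(ws, 8, 8)
  seen <- unlist(lapply(batches, `[[`, "t_index"))
  expect_equal(seen, ws$t_index[seq_along(seen)])   # exact prefix, no repeats
})

test_that("overlapping batches repeat each vector between 1 and ceil(B/stride) times", {
  rec <- ts_record(matrix(rnorm(60), 60, 1), rep(0L, 60), n_classes = 2)
  ws <- sliding_window(rec, window_spec(4, 2))
  B <- 8L; stride <- 3L
  batches <- make_minibatches(ws, B, stride)
  tab <- table(unlist(lapply(batches, `[[`, "t_index")))
  expect_true(all(tab >= 1L & tab <= ceiling(B / stride)))
  ## interior vectors reach the full multiplicity
  expect_true(any(tab == ceiling(B / stride)))
})

test_that("shuffling permutes batches but never their internal order", {
  rec <- ts_record(matrix(rnorm(500), 250, 2), rep(0L, 250), n_classes = 2)
  ws <- sliding_window(rec, window_spec(4, 2))
  batches <- make_minibatches(ws, 8, 1)    # > 100 batches
  sh0 <- shuffle_minibatches(batches, seed = 0)
  for (b in sh0) expect_true(all(diff(b$t_index) == 2L))
  expect_identical(shuffle_minibatches(batches, seed = 0), sh0)
  sh1 <- shuffle_minibatches(batches, seed = 1)
  expect_false(identical(sapply(sh0, function(b) b$t_index[1]),
                         sapply(sh1, function(b) b$t_index[1])))
})

test_that("fold standardization uses training statistics only", {
  rec <- make_step_record(N = 240, C = 2, seed = 2)
  ws <- sliding_window(rec, window_spec(8, 4))
  batches <- make_minibatches(ws, 8, 8)
  std <- standardize_fold(batches[1:4], batches[5:7])
  Xtr <- do.call(rbind, lapply(std$train, `[[`, "features"))
  expect_lt(max(abs(colMeans(Xtr))), 1e-9)
  expect_lt(max(abs(apply(Xtr, 2, sd) - 1)), 1e-9)
  ## held-out batches keep a generally nonzero mean under train statistics
  Xte <- do.call(rbind, lapply(std$apply_to, `[[`, "features"))
  expect_gt(max(abs(colMeans(Xte))), 0.1)
})

test_that("constant features pass through standardization unchanged", {
  rec <- ts_record(cbind(rnorm(40), 7), rep(0L, 40), n_classes = 2)
  ws <- sliding_window(rec, window_spec(4, 4))
  batches <- make_minibatches(ws, 5, 5)
  std <- standardize_fold(batches)
  Xtr <- do.call(rbind, lapply(std$train, `[[`, "features"))
  expect_true(all(Xtr[, 5:8] == 7))
})
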