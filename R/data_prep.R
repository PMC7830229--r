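#' Labelled multichannel time series
#'
#' Container for a uniformly sampled, per-sample-labelled multichannel
#' signal: an `N x C` numeric matrix of channel values plus an integer class
#' label for every sample.  Class ids are 0-based (`0 .. n_classes - 1`),
#' matching the label columns of the UCI-style CSV files the package reads.
#'
#' @param values numeric matrix, `N` samples by `C` channels.
#' @param labels integer vector of length `N`, class ids in
#'   `0 .. n_classes - 1`.
#' @param n_classes number of classes `K`; defaults to `max(labels) + 1`.
#' @return An object of class `"ts_record"`: a list with elements `values`,
#'   `labels` and `n_classes`.
#' @examples
#' rec <- ts_record(matrix(rnorm(40), 20, 2), rep(c(0L, 1L), each = 10))
#' rec
#' @export
ts_record <- function(values, labels, n_classes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_dtcn("'values' must have at least one sample and one channel")
  if (length(labels) != nrow(values))
    stop_dtcn("need one label per sample: %d labels for %d samples",
              length(labels), nrow(values))
  if (!all(is.finite(values)))
    stop_dtcn("'values' must be finite")
  if (anyNA(labels) || any(labels < 0L))
    stop_dtcn("labels must be non-negative integers")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L || any(labels >= n_classes))
    stop_dtcn("labels must lie in [0, n_classes - 1]")
  structure(list(values = values, labels = labels, n_classes = n_classes),
            class = "ts_record")
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("Labelled time series: %d samples, %d channel(s), %d class(es)\n",
              nrow(x$values), ncol(x$values), x$n_classes))
  tab <- tabulate(x$labels + 1L, nbins = x$n_classes)
  cat("Label counts:", paste(sprintf("%d:%d", seq_along(tab) - 1L, tab),
                             collapse = "  "), "\n")
  invisible(x)
}

#' Sliding-window specification
#'
#' Window length `w` and stride `s` (both in samples) of the time-delay
#' representation.  Neighbouring windows overlap whenever `s < w`.
#'
#' @param w window length in samples, `w >= 1`.
#' @param s stride in samples, `1 <= s <= w`.
#' @return An object of class `"window_spec"`.
#' @examples
#' compute_overlap(window_spec(128, 64))  # 50
#' @export
window_spec <- function(w, s) {
  w <- as.integer(w); s <- as.integer(s)
  if (length(w) != 1L || is.na(w) || w < 1L)
    stop_dtcn("invalid window spec: 'w' must be a positive integer")
  if (length(s) != 1L || is.na(s) || s < 1L || s > w)
    stop_dtcn("invalid window spec: need 1 <= s <= w")
  structure(list(w = w, s = s), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("Window spec: w = %d, s = %d (%.4g%% overlap)\n",
              x$w, x$s, compute_overlap(x)))
  invisible(x)
}

#' Percentage overlap of neighbouring windows
#'
#' The overlap between two neighbouring windows of length `w` taken with
#' stride `s` is `(w - s) / w * 100` percent.
#'
#' @param spec a [window_spec()].
#' @return Overlap percentage in `[0, 100)`.
#' @examples
#' compute_overlap(window_spec(128, 64))  # 50% overlap
#' compute_overlap(window_spec(4, 1))     # 75
#' @export
compute_overlap <- function(spec) {
  if (!inherits(spec, "window_spec")) spec <- do.call(window_spec, as.list(spec))
  (spec$w - spec$s) / spec$w * 100
}

#' Time-delay representation of a labelled series
#'
#' Slides a window of length `w` with stride `s` across the series and emits
#' one data vector per window position: the flattened window values
#' (channel-major: all `w` lags of channel 1, then channel 2, ...) together
#' with the per-class count of the sample labels inside the window.  No
#' majority vote is taken here; label counts are carried forward and voting
#' is deferred to the final classifier.
#'
#' Windows are 0-based and half-open: vector `i` covers samples
#' `[i*s, i*s + w)`.  A tail shorter than `w` is dropped.
#'
#' @param record a [ts_record()].
#' @param spec a [window_spec()].
#' @return An object of class `"window_set"`: list with `features`
#'   (`V x w*C` matrix), `label_counts` (`V x K` integer matrix), `t_index`
#'   (0-based start sample of each window), and the originating `w`, `s`,
#'   `n_channels`, `n_classes`.
#' @examples
#' rec <- ts_record(matrix(rnorm(20), 10, 2), rep(0L, 10), n_classes = 2)
#' sliding_window(rec, window_spec(4, 2))$t_index  # 0 2 4 6
#' @export
sliding_window <- function(record, spec) {
  stopifnot(inherits(record, "ts_record"), inherits(spec, "window_spec"))
  N <- nrow(record$values); C <- ncol(record$values)
  w <- spec$w; s <- spec$s; K <- record$n_classes
  if (N < w)
    stop_dtcn("series too short for windowing: N = %d samples < w = %d (no window fits)",
              N, w)
  V <- (N - w) %/% s + 1L
  starts <- (seq_len(V) - 1L) * s                      # 0-based
  idx <- outer(seq_len(w), starts, "+")                # w x V, 1-based rows
  features <- matrix(0, V, w * C)
  for (ch in seq_len(C))
    features[, (ch - 1L) * w + seq_len(w)] <-
      t(matrix(record$values[, ch][idx], nrow = w))
  ## windowed label counts from cumulative one-hot sums
  onehot <- matrix(0L, N, K)
  onehot[cbind(seq_len(N), record$labels + 1L)] <- 1L
  csum <- rbind(0L, apply(onehot, 2L, cumsum))
  label_counts <- csum[starts + w + 1L, , drop = FALSE] -
    csum[starts + 1L, , drop = FALSE]
  storage.mode(label_counts) <- "integer"
  structure(list(features = features, label_counts = label_counts,
                 t_index = starts, w = w, s = s, n_channels = C,
                 n_classes = K),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d vectors of length %d (w = %d, s = %d, %d channels, %d classes)\n",
              nrow(x$features), ncol(x$features), x$w, x$s,
              x$n_channels, x$n_classes))
  invisible(x)
}

new_minibatch <- function(features, label_counts, t_index, n_classes) {
  structure(list(features = features, label_counts = label_counts,
                 t_index = t_index, n_classes = n_classes),
            class = "minibatch")
}

#' Overlapping mini-batches of windowed data
#'
#' Second stage of the two-stage sliding window: a window of `size`
#' consecutive data vectors slides along the window set with stride
#' `batch_stride`, producing mini-batches that overlap their neighbours and
#' keep their vectors in natural time order.  Overlap makes the contribution
#' of individual vectors unequal within one batch but nearly equal over the
#' whole batch sequence.
#'
#' @param windows a `"window_set"` from [sliding_window()].
#' @param size mini-batch size `B` (number of data vectors per batch).
#' @param batch_stride stride of the second-stage window, `1 <= stride <= B`;
#'   default `max(1, floor(size/2))`, i.e. 50\% batch overlap.
#' @return List of `"minibatch"` objects, each with `features` (`B x w*C`),
#'   `label_counts` (`B x K`), `t_index`.
#' @examples
#' rec <- ts_record(matrix(rnorm(120), 60, 2), rep(0:1, 30), n_classes = 2)
#' ws <- sliding_window(rec, window_spec(4, 2))
#' length(make_minibatches(ws, size = 8, batch_stride = 4))
#' @export
make_minibatches <- function(windows, size,
                             batch_stride = max(1L, size %/% 2L)) {
  stopifnot(inherits(windows, "window_set"))
  size <- as.integer(size); batch_stride <- as.integer(batch_stride)
  V <- nrow(windows$features)
  if (size < 1L || V < size)
    stop_dtcn("too few data vectors for mini-batches: have %d, need >= %d", V, size)
  if (batch_stride < 1L || batch_stride > size)
    stop_dtcn("need 1 <= batch_stride <= size")
  n <- (V - size) %/% batch_stride + 1L
  lapply(seq_len(n) - 1L, function(j) {
    rows <- j * batch_stride + seq_len(size)
    new_minibatch(windows$features[rows, , drop = FALSE],
                  windows$label_counts[rows, , drop = FALSE],
                  windows$t_index[rows], windows$n_classes)
  })
}

#' @export
print.minibatch <- function(x, ...) {
  cat(sprintf("Mini-batch: %d vectors x %d features, t_index %d..%d\n",
              nrow(x$features), ncol(x$features), x$t_index[1L],
              x$t_index[length(x$t_index)]))
  invisible(x)
}

#' Shuffle mini-batches, preserving within-batch time order
#'
#' Permutes the order of whole mini-batches to shatter the long-range label
#' sequence while leaving each batch's internal (short-term) time order
#' untouched, so concatenation inside a batch stays meaningful.
#'
#' @param batches list of mini-batches.
#' @param seed integer seed; the same seed always yields the same
#'   permutation, and the caller's RNG state is left untouched.
#' @return The permuted list.
#' @export
shuffle_minibatches <- function(batches, seed) {
  rng <- rng_stream(seed)
  perm <- rng$draw(function() sample.int(length(batches)))
  batches[perm]
}

#' Per-feature standardization fitted on training batches
#'
#' Estimates a per-feature mean and standard deviation from the training
#' mini-batches only and applies the z-score transform to both the training
#' batches and (optionally) held-out batches, as done fold-by-fold during
#' cross-validation.  Features with zero spread pass through unchanged.
#'
#' @param train list of training mini-batches (statistics source).
#' @param apply_to optional list of held-out mini-batches transformed with
#'   the training statistics.
#' @return List with `train`, `apply_to` (transformed batches), `center`,
#'   `scale`.
#' @export
standardize_fold <- function(train, apply_to = NULL) {
  if (length(train) == 0L) stop_dtcn("no training batches to standardize on")
  X <- do.call(rbind, lapply(train, `[[`, "features"))
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  const <- !is.finite(scale) | scale == 0
  center[const] <- 0          # constant feature: pass through unchanged
  scale[const] <- 1
  list(train = apply_standardization(train, center, scale),
       apply_to = if (!is.null(apply_to))
         apply_standardization(apply_to, center, scale),
       center = center, scale = scale)
}

apply_standardization <- function(batches, center, scale) {
  lapply(batches, function(b) {
    b$features <- sweep(sweep(b$features, 2L, center, "-"), 2L, scale, "/")
    b
  })
}
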