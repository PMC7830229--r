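#' Fit a deep temporal convolution network
#'
#' End-to-end training pipeline for per-sample-labelled multichannel time
#' series: time-delay windowing with label-count tallies, two-stage
#' overlapping mini-batch construction in natural time order, per-feature
#' standardization, greedy RBM pretraining of the hidden connections, and
#' supervised fine-tuning by backpropagation with split-slide-add gradient
#' routing across every concatenation sublayer.  Whole mini-batches are
#' reshuffled every epoch (deterministically from `seed`) while the order
#' inside each batch is preserved, so long-range label order is shattered
#' but short-term temporal context survives for concatenation.
#'
#' @param x a [ts_record()], or a numeric `N x C` matrix with `labels`.
#' @param labels integer class ids (0-based) when `x` is a matrix.
#' @param window a [window_spec()] or a length-2 vector `c(w, s)`.
#' @param hidden hidden-layer widths.
#' @param ts time steps of every concatenation sublayer (`ts = 1` fits a
#'   plain DBN-DNN).
#' @param batch_size mini-batch size `B`; at least `8` when `ts > 1` so the
#'   concatenation sublayers have instances to join.
#' @param batch_stride second-stage stride; default `B/2` (50\% overlap).
#' @param epochs fine-tuning epochs.
#' @param lr fine-tuning learning rate.
#' @param momentum classical momentum coefficient.
#' @param pretrain logical: pretrain hidden connections as a stack of RBMs.
#' @param pretrain_epochs,pretrain_lr,cd_k pretraining schedule: epochs,
#'   learning rate, CD Gibbs steps.
#' @param standardize logical: z-score features (statistics stored for
#'   prediction).
#' @param soft_targets use count-proportional soft targets instead of hard
#'   majority-vote one-hot targets.
#' @param n_classes optional class count when `x` is a matrix.
#' @param seed master seed: initialisation, shuffling, tie-breaking and CD
#'   sampling draw from independent streams derived from it.
#' @return Object of class `"dtcn"` with components `params`, `window`,
#'   `center`/`scale`, `loss` (per-epoch mean training loss),
#'   `train_accuracy` (percent, surviving-row accuracy on the training
#'   batches), `config`, `call`.
#' @seealso [predict.dtcn()], [crossval()], [ts_sweep()]
#' @examples
#' rec <- generate_series(synth_spec(n_samples = 3000, seed = 3))
#' fit <- dtcn(rec, window = c(16, 8), hidden = c(8, 8), ts = 2,
#'             epochs = 5, pretrain_epochs = 2, seed = 1)
#' fit
#' @export
dtcn <- function(x, labels = NULL, window = c(16L, 8L), hidden = c(20L, 20L, 20L),
                 ts = 2L, batch_size = 18L, batch_stride = NULL,
                 epochs = 60L, lr = 0.05, momentum = 0.9,
                 pretrain = TRUE, pretrain_epochs = 10L, pretrain_lr = 0.05,
                 cd_k = 1L, standardize = TRUE, soft_targets = FALSE,
                 n_classes = NULL, seed = 1L) {
  cl <- match.call()
  record <- if (inherits(x, "ts_record")) x else ts_record(x, labels, n_classes)
  spec <- if (inherits(window, "window_spec")) window else
    window_spec(window[1L], window[2L])
  if (is.null(batch_stride)) batch_stride <- max(1L, batch_size %/% 2L)
  if (ts > 1L && batch_size < 8L)
    stop_dtcn("batch_size must be >= 8 when ts > 1 (concatenation needs instances to join)")

  windows <- sliding_window(record, spec)
  batches <- make_minibatches(windows, batch_size, batch_stride)
  center <- scale <- NULL
  if (standardize) {
    std <- standardize_fold(batches)
    batches <- std$train
    center <- std$center; scale <- std$scale
  }

  sizes <- c(ncol(windows$features), hidden, record$n_classes)
  params <- dtcn_params(sizes, ts = ts, seed = derive_seed(seed, 1L))
  if (pretrain)
    params <- pretrain_stack(params, batches,
                             list(epochs = pretrain_epochs, lr = pretrain_lr,
                                  k = cd_k, seed = derive_seed(seed, 2L)))

  cfg <- list(lr = lr, momentum = momentum, soft_targets = soft_targets,
              epochs = epochs, seed = seed)
  trained <- train_network(params, batches, cfg)

  acc <- evaluate_batches(trained$params, batches,
                          tie_seed = derive_seed(seed, 4L))
  structure(list(params = trained$params, window = spec,
                 center = center, scale = scale,
                 loss = trained$loss, train_accuracy = acc$accuracy,
                 n_batches = length(batches), n_classes = record$n_classes,
                 n_channels = ncol(record$values),
                 config = c(cfg, list(batch_size = batch_size,
                                      batch_stride = batch_stride,
                                      pretrain = pretrain,
                                      pretrain_epochs = pretrain_epochs,
                                      pretrain_lr = pretrain_lr, cd_k = cd_k,
                                      standardize = standardize)),
                 call = cl),
            class = "dtcn")
}

## fine-tuning loop: epoch-wise deterministic reshuffle of whole batches,
## one backprop update per batch; returns params + per-epoch mean loss
train_network <- function(params, batches, config) {
  epochs <- if (is.null(config$epochs)) 30L else as.integer(config$epochs)
  seed <- if (is.null(config$seed)) 1L else config$seed
  tie_rng <- rng_stream(derive_seed(seed, 3L))
  cfg <- list(lr = config$lr, momentum = config$momentum,
              soft_targets = config$soft_targets, tie_rng = tie_rng)
  state <- NULL
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    order_seed <- derive_seed(seed, 10L + e)
    shuffled <- shuffle_minibatches(batches, order_seed)
    batch_loss <- numeric(length(shuffled))
    for (i in seq_along(shuffled)) {
      upd <- backprop_update(params, shuffled[[i]], cfg, state)
      params <- upd$params
      state <- upd$state
      batch_loss[i] <- upd$loss
    }
    loss[e] <- mean(batch_loss)
  }
  list(params = params, loss = loss)
}

#' Accuracy of a parameter set over mini-batches
#'
#' Runs the forward pass on every batch and scores the fraction of
#' surviving terminal rows whose arg-max softmax class equals the majority
#' vote of that row's pooled label counts (the accuracy denominator used
#' throughout the package).
#'
#' @param params a [dtcn_params()].
#' @param batches list of mini-batches.
#' @param tie_seed seed of the vote tie-break stream.
#' @return List: `accuracy` (percent), `n_rows` (surviving rows scored),
#'   `predicted`, `target` (0-based ids, concatenated over batches).
#' @export
evaluate_batches <- function(params, batches, tie_seed = 1L) {
  rng <- rng_stream(tie_seed)
  pred <- integer(0); targ <- integer(0)
  for (b in batches) {
    fwd <- forward_dtcn(params, b)
    pred <- c(pred, max.col(fwd$probs, ties.method = "first") - 1L)
    targ <- c(targ, vote_rows(fwd$pooled_counts, rng))
  }
  list(accuracy = 100 * mean(pred == targ), n_rows = length(pred),
       predicted = pred, target = targ)
}

#' @export
print.dtcn <- function(x, ...) {
  cat("Deep temporal convolution network\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Layers [%s], TS = %d, %d weight parameters\n",
              paste(x$params$layer_sizes, collapse = ", "), x$params$ts,
              param_count(x$params$layer_sizes, x$params$ts)))
  cat(sprintf("Trained %d epochs on %d mini-batches; final loss %.4f\n",
              length(x$loss), x$n_batches, x$loss[length(x$loss)]))
  cat(sprintf("Training accuracy (surviving rows): %.2f%%\n", x$train_accuracy))
  invisible(x)
}

#' @export
summary.dtcn <- function(object, ...) {
  fi <- connection_fan_in(object$params$layer_sizes, object$params$ts)
  fo <- object$params$layer_sizes[-1L]
  conn <- data.frame(connection = seq_along(fo), fan_in = fi, fan_out = fo,
                     weights = fi * fo)
  structure(list(fit = object, connections = conn), class = "summary.dtcn")
}

#' @export
print.summary.dtcn <- function(x, ...) {
  print(x$fit)
  cat("\nConnections (fan-in includes the TS factor after each concatenation):\n")
  print(x$connections, row.names = FALSE)
  cat(sprintf("\nWindow: w = %d, s = %d (%.4g%% overlap); batch size %d, stride %d\n",
              x$fit$window$w, x$fit$window$s, compute_overlap(x$fit$window),
              x$fit$config$batch_size, x$fit$config$batch_stride))
  invisible(x)
}

#' @export
coef.dtcn <- function(object, ...) {
  list(weights = object$params$W, biases = object$params$b)
}

#' @export
plot.dtcn <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 16,
       xlab = "Epoch", ylab = "Mean training cross-entropy",
       main = "DTCN fine-tuning loss", ...)
  invisible(x)
}

#' Predict classes for new multichannel series
#'
#' Applies the fitted pipeline to new data: windowing with the stored
#' window spec, standardization with the stored training statistics,
#' mini-batch construction, and the DTCN forward pass.  Predictions are
#' made for the surviving terminal rows of each mini-batch.
#'
#' @param object a fitted [dtcn()] model.
#' @param newdata a [ts_record()] or a numeric `N x C` matrix (labels, if
#'   present, are ignored for prediction).
#' @param type `"class"` for 0-based class ids, `"prob"` for softmax rows.
#' @param ... unused.
#' @return Integer vector of class ids, or a matrix of class probabilities.
#' @export
predict.dtcn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  batches <- prepare_batches(object, newdata)
  probs <- do.call(rbind, lapply(batches, function(b)
    forward_dtcn(object$params, b)$probs))
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}

## rebuild the training-time batch pipeline around new data
prepare_batches <- function(object, newdata) {
  record <- if (inherits(newdata, "ts_record")) newdata else
    ts_record(as.matrix(newdata), rep(0L, nrow(as.matrix(newdata))),
              n_classes = object$n_classes)
  if (record$n_classes != object$n_classes && inherits(newdata, "ts_record"))
    stop_dtcn("newdata has %d classes but the model was fitted with %d",
              record$n_classes, object$n_classes)
  windows <- sliding_window(record, object$window)
  batches <- make_minibatches(windows, object$config$batch_size,
                              object$config$batch_stride)
  if (!is.null(object$center))
    batches <- apply_standardization(batches, object$center, object$scale)
  batches
}

#' Score a fitted model on labelled data
#'
#' Convenience wrapper: rebuilds mini-batches from a labelled record and
#' returns the surviving-row accuracy against majority-voted targets.
#'
#' @param object a fitted [dtcn()].
#' @param newdata a labelled [ts_record()].
#' @param tie_seed vote tie-break seed.
#' @return Accuracy in percent.
#' @export
dtcn_score <- function(object, newdata, tie_seed = 1L) {
  batches <- prepare_batches(object, newdata)
  evaluate_batches(object$params, batches, tie_seed = tie_seed)$accuracy
}
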