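#' k-fold cross-validation of a DTCN on a labelled series
#'
#' Folds are contiguous blocks of the mini-batch sequence, fixed before any
#' shuffling, so no mini-batch ever spans the train/test boundary.  Within
#' each fold the full training pipeline runs from scratch on the training
#' batches only: per-feature standardization statistics, RBM pretraining
#' and fine-tuning all derive from the training folds, and the held-out
#' batches are transformed with the training statistics and scored by
#' surviving-row accuracy against majority-voted targets.
#'
#' @param record a labelled [ts_record()].
#' @param k number of folds.
#' @param window,hidden,ts,batch_size,batch_stride,epochs,lr,momentum,pretrain,pretrain_epochs,pretrain_lr,cd_k,soft_targets
#'   as in [dtcn()].
#' @param seed master seed; all fold-level randomness derives from it, so
#'   the same seed and data reproduce the result exactly.
#' @return Object of class `"dtcn_cv"`: `per_fold` (accuracy percent per
#'   fold), `mean`, `sd`, `config` snapshot.
#' @examples
#' rec <- generate_series(synth_spec(n_samples = 4000, seed = 5))
#' cv <- crossval(rec, k = 3, window = c(16, 8), hidden = c(8, 8), ts = 2,
#'                epochs = 5, pretrain_epochs = 2, seed = 1)
#' cv
#' @export
crossval <- function(record, k = 10L, window = c(16L, 8L),
                     hidden = c(20L, 20L, 20L), ts = 1L, batch_size = 18L,
                     batch_stride = NULL, epochs = 60L, lr = 0.05,
                     momentum = 0.9, pretrain = TRUE, pretrain_epochs = 10L,
                     pretrain_lr = 0.05, cd_k = 1L, soft_targets = FALSE,
                     seed = 1L) {
  stopifnot(inherits(record, "ts_record"))
  spec <- if (inherits(window, "window_spec")) window else
    window_spec(window[1L], window[2L])
  if (is.null(batch_stride)) batch_stride <- max(1L, batch_size %/% 2L)
  windows <- sliding_window(record, spec)
  batches <- make_minibatches(windows, batch_size, batch_stride)
  nb <- length(batches)
  if (nb < k)
    stop_dtcn("insufficient data: %d mini-batches for %d folds", nb, k)
  ## contiguous block folds over the (time-ordered) batch sequence
  fold_id <- rep(seq_len(k), times = diff(round(seq(0, nb, length.out = k + 1))))

  cfg <- list(hidden = hidden, ts = ts, epochs = epochs, lr = lr,
              momentum = momentum, pretrain = pretrain,
              pretrain_epochs = pretrain_epochs, pretrain_lr = pretrain_lr,
              cd_k = cd_k, soft_targets = soft_targets,
              n_input = ncol(windows$features), n_classes = record$n_classes)
  per_fold <- vapply(seq_len(k), function(f) {
    run_fold(batches[fold_id != f], batches[fold_id == f], cfg,
             seed = derive_seed(seed, 1000L + f))
  }, numeric(1L))

  structure(list(per_fold = per_fold, mean = mean(per_fold),
                 sd = stats::sd(per_fold), k = k,
                 config = c(cfg, list(window = spec, batch_size = batch_size,
                                      batch_stride = batch_stride,
                                      seed = seed))),
            class = "dtcn_cv")
}

## one fold: standardize on train, pretrain, fine-tune, score held-out
## batches; nothing from `test` reaches training
run_fold <- function(train, test, cfg, seed, return_fit = FALSE) {
  std <- standardize_fold(train, test)
  sizes <- c(cfg$n_input, cfg$hidden, cfg$n_classes)
  params <- dtcn_params(sizes, ts = cfg$ts, seed = derive_seed(seed, 1L))
  if (isTRUE(cfg$pretrain))
    params <- pretrain_stack(params, std$train,
                             list(epochs = cfg$pretrain_epochs,
                                  lr = cfg$pretrain_lr, k = cfg$cd_k,
                                  seed = derive_seed(seed, 2L)))
  trained <- train_network(params, std$train,
                           list(lr = cfg$lr, momentum = cfg$momentum,
                                soft_targets = cfg$soft_targets,
                                epochs = cfg$epochs, seed = seed))
  acc <- evaluate_batches(trained$params, std$apply_to,
                          tie_seed = derive_seed(seed, 4L))$accuracy
  if (return_fit)
    list(accuracy = acc, params = trained$params,
         center = std$center, scale = std$scale)
  else acc
}

#' @export
print.dtcn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (TS = %d, hidden [%s])\n",
              x$k, x$config$ts, paste(x$config$hidden, collapse = ", ")))
  cat("Per-fold accuracy (%):",
      paste(sprintf("%.2f", x$per_fold), collapse = "  "), "\n")
  cat(sprintf("Mean %.2f%%, SD %.2f%%\n", x$mean, x$sd))
  invisible(x)
}

#' Sweep the time-steps hyperparameter, with matched plain-network baselines
#'
#' Runs [crossval()] once per requested `TS` value with matched seeds, and
#' (optionally) once more per `TS > 1` for the complexity-matched plain
#' network from [equivalent_dbn_config()] run at `TS = 1`, so the effect of
#' temporal-context concatenation can be separated from parameter count.
#'
#' @param record a labelled [ts_record()].
#' @param ts_values time-steps values to sweep.
#' @param include_equivalent also run the complexity-matched `TS = 1`
#'   baselines.
#' @param ... passed to [crossval()] (all values but `ts`).
#' @return Object of class `"dtcn_sweep"`: a data frame with one row per
#'   run (`model`, `ts`, `hidden`, `param_count`, `mean`, `sd`) carrying
#'   the full per-fold matrix as attribute `"per_fold"`.
#' @export
ts_sweep <- function(record, ts_values = c(1L, 2L, 5L),
                     include_equivalent = TRUE, ...) {
  args <- list(...)
  hidden <- if (is.null(args$hidden)) c(20L, 20L, 20L) else args$hidden
  rows <- list(); per_fold <- list()
  add_run <- function(model, ts, hid) {
    cv <- do.call(crossval, c(list(record = record, ts = ts),
                              modifyList(args, list(hidden = hid))))
    sizes <- c(cv$config$n_input, hid, cv$config$n_classes)
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, ts = ts, hidden = paste(hid, collapse = "-"),
      param_count = param_count(sizes, ts), mean = cv$mean, sd = cv$sd)
    per_fold[[length(per_fold) + 1L]] <<- cv$per_fold
  }
  for (ts in ts_values) add_run("dtcn", ts, hidden)
  if (include_equivalent) {
    win <- if (is.null(args$window)) c(16L, 8L) else args$window
    if (!inherits(win, "window_spec")) win <- window_spec(win[1L], win[2L])
    n_input <- ncol(record$values) * win$w
    for (ts in setdiff(ts_values, 1L)) {
      sizes <- c(n_input, hidden, record$n_classes)
      add_run("equivalent", 1L, equivalent_dbn_config(sizes, ts))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_fold") <- do.call(rbind, per_fold)
  class(out) <- c("dtcn_sweep", "data.frame")
  out
}

#' @export
print.dtcn_sweep <- function(x, ...) {
  cat("Time-steps sweep (cross-validated accuracy, %):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.dtcn_sweep <- function(x, ...) {
  pf <- t(attr(x, "per_fold"))
  labels <- sprintf("%s TS=%d", x$model, x$ts)
  graphics::matplot(pf, type = "b", pch = 16, lty = 1,
                    xlab = "Fold", ylab = "Accuracy (%)",
                    main = "Cross-validated accuracy by fold", ...)
  graphics::legend("bottomleft", legend = labels, col = seq_len(ncol(pf)),
                   pch = 16, lty = 1, cex = 0.8)
  invisible(x)
}
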