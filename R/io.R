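#' Read a labelled multichannel series from delimited text
#'
#' Expects one row per sample: `C` numeric channel columns followed by one
#' integer class-label column (0-based ids).  A header row is detected
#' automatically unless `header` is given.
#'
#' @param file path to the delimited file.
#' @param delim field delimiter.
#' @param header logical, or `NA` (default) to auto-detect.
#' @param n_classes optional class count (defaults to `max(label) + 1`).
#' @return A [ts_record()].
#' @export
read_ts_csv <- function(file, delim = ",", header = NA, n_classes = NULL) {
  if (is.na(header)) {
    first <- strsplit(readLines(file, n = 1L), delim, fixed = TRUE)[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(first)))
  }
  df <- utils::read.table(file, sep = delim, header = header)
  if (ncol(df) < 2L)
    stop_dtcn("need at least one channel column and one label column")
  lab <- df[[ncol(df)]]
  ts_record(as.matrix(df[, -ncol(df), drop = FALSE]), as.integer(lab),
            n_classes = n_classes)
}

#' Write a labelled series as delimited text
#'
#' @param record a [ts_record()].
#' @param file output path.
#' @param delim field delimiter.
#' @param header write a header row (`ch1..chC, label`).
#' @export
write_ts_csv <- function(record, file, delim = ",", header = TRUE) {
  stopifnot(inherits(record, "ts_record"))
  df <- as.data.frame(record$values)
  names(df) <- paste0("ch", seq_len(ncol(df)))
  df$label <- record$labels
  utils::write.table(df, file, sep = delim, row.names = FALSE,
                     col.names = header, quote = FALSE)
}

#' Read a labelled series from an ARFF file
#'
#' Reads UCI-style ARFF files (numeric attributes plus a nominal or integer
#' class as the last attribute) via \pkg{foreign}.  Nominal class levels
#' are mapped to 0-based ids in level order.
#'
#' @param file path to the ARFF file.
#' @param n_classes optional class count.
#' @return A [ts_record()].
#' @export
read_ts_arff <- function(file, n_classes = NULL) {
  if (!requireNamespace("foreign", quietly = TRUE))
    stop_dtcn("reading ARFF files requires the 'foreign' package")
  df <- foreign::read.arff(file)
  lab <- df[[ncol(df)]]
  labels <- if (is.factor(lab)) as.integer(lab) - 1L else as.integer(lab)
  vals <- as.matrix(as.data.frame(lapply(df[, -ncol(df), drop = FALSE],
                                         as.numeric)))
  ts_record(vals, labels, n_classes = n_classes)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys (all optional): `window.w`, `window.s`, `batch.size`,
#' `batch.stride`, `seed`, `ts`, `hidden`, `epochs`, `lr`, `momentum`, and
#' `pretrain.enabled`, `pretrain.epochs`, `pretrain.lr`, `pretrain.k`.
#'
#' @param file path to a YAML file.
#' @return A named list of arguments suitable for [dtcn()]/[crossval()].
#' @export
read_dtcn_config <- function(file) {
  y <- yaml::read_yaml(file)
  out <- list()
  if (!is.null(y$window)) out$window <- c(y$window$w, y$window$s)
  if (!is.null(y$batch$size)) out$batch_size <- y$batch$size
  if (!is.null(y$batch$stride)) out$batch_stride <- y$batch$stride
  for (key in c("seed", "ts", "hidden", "epochs", "lr", "momentum"))
    if (!is.null(y[[key]])) out[[key]] <- y[[key]]
  if (!is.null(y$pretrain)) {
    if (!is.null(y$pretrain$enabled)) out$pretrain <- isTRUE(y$pretrain$enabled)
    if (!is.null(y$pretrain$epochs)) out$pretrain_epochs <- y$pretrain$epochs
    if (!is.null(y$pretrain$lr)) out$pretrain_lr <- y$pretrain$lr
    if (!is.null(y$pretrain$k)) out$cd_k <- y$pretrain$k
  }
  out
}

#' Save or load a fitted model as portable JSON
#'
#' Serializes the architecture, time steps, weights, biases and the stored
#' standardization statistics/window spec into a single versioned JSON
#' container, readable by any JSON implementation.
#'
#' @param object a fitted [dtcn()] model or a bare [dtcn_params()].
#' @param path output path.
#' @export
write_dtcn <- function(object, path) {
  params <- if (inherits(object, "dtcn")) object$params else object
  stopifnot(inherits(params, "dtcn_params"))
  payload <- list(format_version = 1L,
                  layer_sizes = params$layer_sizes, ts = params$ts,
                  weights = lapply(params$W, unclass),
                  biases = params$b)
  if (inherits(object, "dtcn"))
    payload <- c(payload, list(center = object$center, scale = object$scale,
                               window = list(w = object$window$w,
                                             s = object$window$s),
                               n_classes = object$n_classes,
                               config = object$config[c("batch_size",
                                                        "batch_stride")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dtcn
#' @return `read_dtcn()` returns a `"dtcn_params"` object (with prediction
#'   metadata attached as attributes when present in the file).
#' @export
read_dtcn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) || p$format_version != 1L)
    stop_dtcn("unsupported model container version")
  params <- structure(list(layer_sizes = as.integer(p$layer_sizes),
                           ts = as.integer(p$ts),
                           W = lapply(p$weights, as.matrix),
                           b = lapply(p$biases, as.numeric)),
                      class = "dtcn_params")
  for (extra in c("center", "scale", "window", "n_classes", "config"))
    if (!is.null(p[[extra]])) attr(params, extra) <- p[[extra]]
  params
}
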