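#' Network parameters of a deep temporal convolution network
#'
#' A DTCN is a feed-forward sigmoid network whose hidden-layer activations
#' are rearranged, after every hidden layer, by a concatenation sublayer:
#' `TS` consecutive activation rows of a mini-batch are joined horizontally
#' into one row, so the next connection sees the temporal context of `TS`
#' neighbouring data instances.  The weights of connection `i > 1` therefore
#' attach to the concatenation sublayer and have `TS * n[i-1]` input units;
#' the first connection attaches to the raw time-delay input (which already
#' encodes temporal context) and is never concatenated.  At `TS = 1` the
#' network reduces exactly to a plain DBN-DNN/MLP.
#'
#' @param layer_sizes integer vector `c(n0, n1, ..., nL, K)`: input width,
#'   hidden widths, number of classes (softmax width).
#' @param ts time steps `TS >= 1`: how many consecutive instances each
#'   concatenation joins.
#' @param seed seed for the weight initialisation stream.
#' @param init_sd if `NULL` (default), connection weights are drawn
#'   `N(0, 1/fan_in)`; otherwise `N(0, init_sd^2)`.
#' @return Object of class `"dtcn_params"`: `layer_sizes`, `ts`, lists `W`
#'   (one `fan_in x fan_out` matrix per connection) and `b` (one bias vector
#'   per connection output).
#' @export
dtcn_params <- function(layer_sizes, ts = 1L, seed = 1L, init_sd = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  ts <- as.integer(ts)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L))
    stop_dtcn("'layer_sizes' must be positive widths: input, hidden..., classes")
  if (ts < 1L) stop_dtcn("'ts' must be >= 1")
  fi <- connection_fan_in(layer_sizes, ts)
  fo <- layer_sizes[-1L]
  rng <- rng_stream(seed)
  W <- vector("list", length(fo))
  for (i in seq_along(fo)) {
    sd_i <- if (is.null(init_sd)) 1 / sqrt(fi[i]) else init_sd
    W[[i]] <- rng$draw(function() matrix(stats::rnorm(fi[i] * fo[i], sd = sd_i),
                                         fi[i], fo[i]))
  }
  b <- lapply(fo, function(n) numeric(n))
  structure(list(layer_sizes = layer_sizes, ts = ts, W = W, b = b),
            class = "dtcn_params")
}

## fan-in of each connection: n0 for the first, TS * n_i after each
## concatenation sublayer
connection_fan_in <- function(layer_sizes, ts) {
  n_in <- layer_sizes[-length(layer_sizes)]
  c(n_in[1L], ts * n_in[-1L])
}

#' @export
print.dtcn_params <- function(x, ...) {
  cat(sprintf("DTCN parameters: layers [%s], TS = %d, %d weights\n",
              paste(x$layer_sizes, collapse = ", "), x$ts,
              param_count(x$layer_sizes, x$ts)))
  invisible(x)
}

#' Concatenation sublayer: join TS consecutive rows
#'
#' Output row `r` is the horizontal join of input rows `r, r+1, ...,
#' r+TS-1`, so a matrix of `R` time-ordered instance rows becomes
#' `R - TS + 1` rows of width `TS * H`.  At `TS = 1` this is the identity.
#'
#' @param mat instance-major numeric matrix, rows in natural time order.
#' @param ts time steps.
#' @return The concatenated matrix.
#' @examples
#' concat_rows(diag(3), ts = 2)  # 2 rows x 6 cols
#' @export
concat_rows <- function(mat, ts) {
  mat <- as.matrix(mat); ts <- as.integer(ts)
  if (ts == 1L) return(mat)
  R <- nrow(mat)
  if (R < ts)
    stop_dtcn("batch too small to concatenate: %d rows < TS = %d", R, ts)
  out <- R - ts + 1L
  do.call(cbind, lapply(seq_len(ts) - 1L,
                        function(j) mat[j + seq_len(out), , drop = FALSE]))
}

#' Pool label counts across a concatenation sublayer
#'
#' Tracks the class composition of concatenated instances: output row `r` is
#' the elementwise sum of input count rows `r .. r+TS-1`.  Row sums multiply
#' by `TS`, so counts are conserved and never voted early (early voting
#' would distort the class distribution that concatenation accumulates).
#'
#' @param counts integer matrix, rows = instances, cols = classes.
#' @param ts time steps.
#' @return Pooled integer matrix with `nrow(counts) - ts + 1` rows.
#' @examples
#' pool_label_counts(rbind(c(1, 0), c(0, 1), c(1, 0)), ts = 3)  # [[2, 1]]
#' @export
pool_label_counts <- function(counts, ts) {
  counts <- as.matrix(counts); ts <- as.integer(ts)
  if (ts == 1L) return(counts)
  if (nrow(counts) < ts)
    stop_dtcn("batch too small to pool: %d rows < TS = %d", nrow(counts), ts)
  out <- nrow(counts) - ts + 1L
  Reduce(`+`, lapply(seq_len(ts) - 1L,
                     function(j) counts[j + seq_len(out), , drop = FALSE]))
}

#' Majority vote over pooled label counts
#'
#' Returns the 0-based class id with the largest count; ties are broken
#' uniformly at random with a dedicated seeded generator, so the same seed
#' and counts always give the same class.
#'
#' @param counts non-negative integer vector (length K) or matrix (rows
#'   voted independently); must not be all zero.
#' @param seed tie-break seed.
#' @return 0-based class id (or vector of ids for a matrix).
#' @examples
#' majority_vote(c(5, 2, 1))        # 0
#' majority_vote(c(0, 0, 7))        # 2
#' @export
majority_vote <- function(counts, seed = 1L) {
  if (is.matrix(counts)) return(vote_rows(counts, rng_stream(seed)))
  vote_rows(matrix(counts, nrow = 1L), rng_stream(seed))[1L]
}

## vote each row of a counts matrix; ties consume the supplied rng stream
vote_rows <- function(counts, rng) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_dtcn("label counts must be non-negative")
  if (any(rowSums(counts) == 0)) stop_dtcn("cannot vote on all-zero counts")
  mx <- apply(counts, 1L, max)
  vapply(seq_len(nrow(counts)), function(r) {
    tied <- which(counts[r, ] == mx[r])
    if (length(tied) == 1L) tied - 1L else
      rng$draw(function() tied[sample.int(length(tied), 1L)]) - 1L
  }, integer(1L))
}

#' Forward pass of a DTCN over one mini-batch
#'
#' Propagates a time-ordered mini-batch through the network: the first
#' connection consumes the raw (time-delay) features, every hidden layer
#' applies the sigmoid, its activation rows are concatenated with `TS`, and
#' the next connection attaches to the concatenation sublayer; the final
#' connection feeds a row-wise softmax.  Each concatenation removes `TS - 1`
#' rows, so with `L` hidden layers `B - L*(TS-1)` instances survive to the
#' softmax.  Per-class label counts are pooled in lockstep with every
#' concatenation and stay row-aligned with the activations.
#'
#' @param params a [dtcn_params()].
#' @param batch a `"minibatch"` (or a bare feature matrix, in which case no
#'   counts are tracked).
#' @return List: `probs` (softmax rows, each summing to 1), `pooled_counts`
#'   (terminal pooled counts, `NULL` for bare matrices), and per-layer
#'   activations `a` (list), concatenated activations `ac` (list), linear
#'   outputs `y` (list) for use by backpropagation.
#' @export
forward_dtcn <- function(params, batch) {
  X <- if (inherits(batch, "minibatch")) batch$features else as.matrix(batch)
  counts <- if (inherits(batch, "minibatch")) batch$label_counts
  ts <- params$ts
  sizes <- params$layer_sizes
  L <- length(sizes) - 2L                       # hidden layers
  need <- L * (ts - 1L) + 1L
  if (nrow(X) < need)
    stop_dtcn("mini-batch too small: %d rows, but TS = %d with %d hidden layers needs B >= %d",
              nrow(X), ts, L, need)
  if (ncol(X) != sizes[1L])
    stop_dtcn("feature width %d does not match input layer size %d",
              ncol(X), sizes[1L])
  a <- ac <- y <- vector("list", L)
  cur <- X
  for (i in seq_len(L)) {
    y[[i]] <- add_rows(cur %*% params$W[[i]], params$b[[i]])
    a[[i]] <- sigmoid(y[[i]])
    ac[[i]] <- concat_rows(a[[i]], ts)
    if (!is.null(counts)) counts <- pool_label_counts(counts, ts)
    cur <- ac[[i]]
  }
  y_out <- add_rows(cur %*% params$W[[L + 1L]], params$b[[L + 1L]])
  list(probs = softmax_rows(y_out), pooled_counts = counts,
       a = a, ac = ac, y = y, input = X)
}

#' Split-slide-add gradient routing (adjoint of concatenation)
#'
#' Redistributes the error contribution at a concatenation sublayer back to
#' the pre-concatenation instances.  The table of per-row contributions is
#' split into `TS` column blocks of width `H`, each block is slid to the
#' time position of the instances it came from, and overlapping entries are
#' added.  Routing is the exact linear adjoint of [concat_rows()]; it
#' conserves the total delta and learns nothing itself.
#'
#' @param table numeric matrix with `pre_rows - ts + 1` rows and `ts * H`
#'   columns: one row per concatenated instance.
#' @param ts time steps used by the concatenation.
#' @param pre_rows number of pre-concatenation instances.
#' @return `pre_rows x H` routed matrix.
#' @export
gradient_route <- function(table, ts, pre_rows) {
  table <- as.matrix(table); ts <- as.integer(ts)
  pre_rows <- as.integer(pre_rows)
  R <- nrow(table)
  if (R != pre_rows - ts + 1L)
    stop_dtcn("routing shape mismatch: %d table rows for pre_rows = %d, TS = %d",
              R, pre_rows, ts)
  if (ncol(table) %% ts != 0L)
    stop_dtcn("table width %d not divisible by TS = %d", ncol(table), ts)
  H <- ncol(table) %/% ts
  if (ts == 1L) return(table)
  out <- matrix(0, pre_rows, H)
  for (j in seq_len(ts) - 1L) {
    block <- table[, j * H + seq_len(H), drop = FALSE]
    rows <- j + seq_len(R)
    out[rows, ] <- out[rows, ] + block
  }
  out
}

#' One backpropagation update with gradient routing
#'
#' Computes the mean cross-entropy of the softmax rows against targets
#' derived from the terminal pooled label counts (hard one-hot majority
#' votes by default, count-proportional soft targets optionally), then
#' propagates deltas backwards: multiplication by the upper connection's
#' weights, [gradient_route()] across each concatenation sublayer, and
#' elementwise multiplication by the sigmoid derivative.  Weights and biases
#' move one plain gradient-descent step (optional classical momentum).
#'
#' @param params a [dtcn_params()].
#' @param batch a `"minibatch"` with label counts.
#' @param config list of training settings: `lr` (step size, required),
#'   `momentum` (default 0), `soft_targets` (default `FALSE`), `tie_rng`
#'   (an internal rng stream) or `tie_seed` (default 1).
#' @param state optional momentum state returned by a previous call.
#' @return List: updated `params`, `loss` (mean cross-entropy before the
#'   update), `state` (momentum velocities).
#' @export
backprop_update <- function(params, batch, config, state = NULL) {
  lr <- config$lr
  if (is.null(lr) || lr <= 0) stop_dtcn("config$lr must be positive")
  momentum <- if (is.null(config$momentum)) 0 else config$momentum
  fwd <- forward_dtcn(params, batch)
  if (is.null(fwd$pooled_counts))
    stop_dtcn("backprop_update needs a mini-batch with label counts")
  targets <- batch_targets(fwd$pooled_counts, config)
  P <- fwd$probs
  R <- nrow(P)
  loss <- -mean(rowSums(targets * log(pmax(P, 1e-12))))
  if (!is.finite(loss))
    stop_dtcn("non-finite loss: learning rate too large or inputs unscaled")

  L <- length(params$layer_sizes) - 2L
  gW <- vector("list", L + 1L); gb <- vector("list", L + 1L)
  delta <- (P - targets) / R                  # d(mean CE)/d(y_softmax)
  gW[[L + 1L]] <- crossprod(fwd$ac[[L]], delta)
  gb[[L + 1L]] <- colSums(delta)
  for (i in rev(seq_len(L))) {
    d_ac <- delta %*% t(params$W[[i + 1L]])   # dE/da at the sublayer
    d_a <- gradient_route(d_ac, params$ts, nrow(fwd$a[[i]]))
    delta <- d_a * fwd$a[[i]] * (1 - fwd$a[[i]])
    inp <- if (i == 1L) fwd$input else fwd$ac[[i - 1L]]
    gW[[i]] <- crossprod(inp, delta)
    gb[[i]] <- colSums(delta)
  }

  if (is.null(state))
    state <- list(vW = lapply(gW, function(g) g * 0),
                  vb = lapply(gb, function(g) g * 0))
  for (i in seq_len(L + 1L)) {
    state$vW[[i]] <- momentum * state$vW[[i]] - lr * gW[[i]]
    state$vb[[i]] <- momentum * state$vb[[i]] - lr * gb[[i]]
    params$W[[i]] <- params$W[[i]] + state$vW[[i]]
    params$b[[i]] <- params$b[[i]] + state$vb[[i]]
  }
  list(params = params, loss = loss, state = state)
}

## training targets from terminal pooled counts: hard one-hot votes
## (default) or count-proportional soft rows
batch_targets <- function(pooled, config) {
  K <- ncol(pooled)
  if (isTRUE(config$soft_targets)) return(pooled / rowSums(pooled))
  rng <- config$tie_rng
  if (is.null(rng))
    rng <- rng_stream(if (is.null(config$tie_seed)) 1L else config$tie_seed)
  ids <- vote_rows(pooled, rng)
  T <- matrix(0, nrow(pooled), K)
  T[cbind(seq_len(nrow(pooled)), ids + 1L)] <- 1
  T
}

#' Weights-only parameter count of a DTCN
#'
#' Sums `fan_in * fan_out` over all connections, with the fan-in of every
#' connection after a concatenation sublayer multiplied by `TS`.  Bias
#' parameters exist in the network but are excluded from this complexity
#' metric, which is the convention under which complexity-matched plain
#' networks are constructed.
#'
#' @param layer_sizes integer vector `c(n0, n1, ..., nL, K)`.
#' @param ts time steps.
#' @return Integer weight count.
#' @examples
#' param_count(c(224, 23, 23, 20, 2), ts = 1)  # 6181
#' param_count(c(224, 20, 20, 20, 2), ts = 2)  # 6160
#' @export
param_count <- function(layer_sizes, ts = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  sum(connection_fan_in(layer_sizes, as.integer(ts)) * layer_sizes[-1L])
}

#' Complexity-matched plain-network configuration
#'
#' Finds the hidden widths of a `TS = 1` network (a plain DBN-DNN) whose
#' weights-only [param_count()] is closest to that of the given DTCN,
#' widening all hidden layers except the last (which keeps its width) and
#' breaking ties toward the smaller count.  Comparing a DTCN against this
#' network isolates the effect of temporal-context concatenation from raw
#' capacity.
#'
#' @param layer_sizes DTCN layer sizes `c(n0, n1, ..., nL, K)`.
#' @param ts the DTCN's time steps.
#' @return Integer vector of equivalent hidden widths (length `L`).
#' @examples
#' equivalent_dbn_config(c(224, 20, 20, 20, 2), ts = 2)  # 23 23 20
#' equivalent_dbn_config(c(224, 20, 20, 20, 2), ts = 5)  # 31 31 20
#' @export
equivalent_dbn_config <- function(layer_sizes, ts) {
  layer_sizes <- as.integer(layer_sizes); ts <- as.integer(ts)
  L <- length(layer_sizes) - 2L
  hidden <- layer_sizes[2L:(L + 1L)]
  if (ts == 1L) return(hidden)
  target <- param_count(layer_sizes, ts)
  widen <- if (L > 1L) seq_len(L - 1L) else 1L
  count_for <- function(h) {
    hs <- hidden; hs[widen] <- h
    param_count(c(layer_sizes[1L], hs, layer_sizes[L + 2L]), 1L)
  }
  h <- 1L
  while (count_for(h) < target) h <- h + 1L
  ## count_for is increasing in h: compare the bracketing widths
  lo <- max(1L, h - 1L)
  best <- if (abs(count_for(lo) - target) <= abs(count_for(h) - target)) lo else h
  hs <- hidden; hs[widen] <- best
  hs
}
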