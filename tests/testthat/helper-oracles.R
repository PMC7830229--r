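## Independent oracles and small fixtures shared across tests.

sigm <- function(x) 1 / (1 + exp(-x))

## Plain fully-connected softmax network, written independently of the
## package internals (explicit loops, no concatenation machinery): the
## reference a TS = 1 network must reproduce.
mlp_forward_oracle <- function(W, b, X) {
  a <- list()
  cur <- X
  for (i in seq_len(length(W) - 1L)) {
    cur <- sigm(sweep(cur %*% W[[i]], 2L, b[[i]], "+"))
    a[[i]] <- cur
  }
  y <- sweep(cur %*% W[[length(W)]], 2L, b[[length(W)]], "+")
  y <- y - apply(y, 1L, max)
  p <- exp(y) / rowSums(exp(y))
  list(probs = p, a = a)
}

## one textbook gradient-descent step on mean cross-entropy; returns
## updated weights and the pre-update loss
mlp_backprop_oracle <- function(W, b, X, targets, lr) {
  L <- length(W) - 1L
  fwd <- mlp_forward_oracle(W, b, X)
  P <- fwd$probs
  loss <- -mean(rowSums(targets * log(pmax(P, 1e-12))))
  delta <- (P - targets) / nrow(P)
  gW <- vector("list", L + 1L); gb <- vector("list", L + 1L)
  gW[[L + 1L]] <- t(fwd$a[[L]]) %*% delta
  gb[[L + 1L]] <- colSums(delta)
  for (i in rev(seq_len(L))) {
    delta <- (delta %*% t(W[[i + 1L]])) * fwd$a[[i]] * (1 - fwd$a[[i]])
    inp <- if (i == 1L) X else fwd$a[[i - 1L]]
    gW[[i]] <- t(inp) %*% delta
    gb[[i]] <- colSums(delta)
  }
  for (i in seq_len(L + 1L)) {
    W[[i]] <- W[[i]] - lr * gW[[i]]
    b[[i]] <- b[[i]] - lr * gb[[i]]
  }
  list(W = W, b = b, loss = loss)
}

## deterministic labelled mini-batch with tie-free counts
make_test_batch <- function(B = 8L, n_in = 6L, K = 2L, w = 4L, seed = 42L) {
  set.seed(seed)
  X <- matrix(rnorm(B * n_in), B, n_in)
  counts <- matrix(0L, B, K)
  counts[cbind(seq_len(B), sample.int(K, B, replace = TRUE))] <- w
  dtcn:::new_minibatch(X, counts, seq_len(B) - 1L, K)
}

## mean cross-entropy of a parameter set on a batch with fixed vote targets
loss_of <- function(params, batch, tie_seed = 99L) {
  fwd <- forward_dtcn(params, batch)
  targets <- dtcn:::batch_targets(fwd$pooled_counts, list(tie_seed = tie_seed))
  -mean(rowSums(targets * log(pmax(fwd$probs, 1e-12))))
}

## a short labelled record with a step change in channel means
make_step_record <- function(N = 200L, C = 2L, seed = 1L) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = N / 2L)
  vals <- matrix(rnorm(N * C), N, C) + labels
  ts_record(vals, labels, n_classes = 2L)
}
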