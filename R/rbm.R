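#' Restricted Boltzmann machine parameters
#'
#' An RBM couples a visible layer to a hidden layer through a bipartite
#' weight matrix.  Visible units are either `"gaussian"` (real-valued,
#' unit-variance standardized signals; used for the raw input layer) or
#' `"bernoulli"` (probabilities in `[0, 1]`; used for concatenated hidden
#' activations in the deeper stack).
#'
#' @param n_vis,n_hid numbers of visible and hidden units.
#' @param visible_type `"gaussian"` or `"bernoulli"`.
#' @param seed seed for the small-Gaussian weight initialisation.
#' @return Object of class `"rbm"`: `W` (`n_vis x n_hid`), `b_vis`, `b_hid`,
#'   `visible_type`.
#' @export
rbm_init <- function(n_vis, n_hid, visible_type = c("gaussian", "bernoulli"),
                     seed = 1L) {
  visible_type <- match.arg(visible_type)
  rng <- rng_stream(seed)
  W <- rng$draw(function() matrix(stats::rnorm(n_vis * n_hid, sd = 0.01),
                                  n_vis, n_hid))
  structure(list(W = W, b_vis = numeric(n_vis), b_hid = numeric(n_hid),
                 visible_type = visible_type),
            class = "rbm")
}

#' One contrastive-divergence (CD-k) update
#'
#' Positive phase: hidden probabilities from the data.  Negative phase: `k`
#' alternating Gibbs steps, sampling binary hidden states and
#' reconstructing visibles as the conditional mean (sigmoid for bernoulli
#' visibles, linear for gaussian visibles).  The gradient estimate is the
#' difference of data and reconstruction correlations; parameters move one
#' step of size `lr` and the mean squared reconstruction error is reported.
#' Labels are never seen: pretraining is fully unsupervised.
#'
#' @param rbm an [rbm_init()] object.
#' @param visible numeric matrix of visible configurations (rows = cases).
#' @param k number of Gibbs alternations, `k >= 1`.
#' @param lr learning rate; `lr = 0` leaves the parameters untouched but
#'   still reports the reconstruction error.
#' @param rng an rng stream (from the caller) or an integer seed for the
#'   hidden-state sampling.
#' @return List: updated `rbm`, `recon_error` (mean squared error of the
#'   final reconstruction).
#' @export
cd_step <- function(rbm, visible, k = 1L, lr = 0.05, rng = 1L) {
  stopifnot(inherits(rbm, "rbm"))
  if (k < 1L) stop_dtcn("'k' must be >= 1")
  if (!inherits(rng, "dtcn_rng")) rng <- rng_stream(rng)
  V0 <- as.matrix(visible)
  n <- nrow(V0)
  h_prob0 <- sigmoid(add_rows(V0 %*% rbm$W, rbm$b_hid))
  h <- rng$draw(function()
    matrix(stats::rbinom(length(h_prob0), 1L, h_prob0), n))
  Vk <- V0; h_probk <- h_prob0
  for (step in seq_len(k)) {
    lin <- add_rows(h %*% t(rbm$W), rbm$b_vis)
    Vk <- if (rbm$visible_type == "gaussian") lin else sigmoid(lin)
    h_probk <- sigmoid(add_rows(Vk %*% rbm$W, rbm$b_hid))
    if (step < k)
      h <- rng$draw(function()
        matrix(stats::rbinom(length(h_probk), 1L, h_probk), n))
  }
  dW <- (crossprod(V0, h_prob0) - crossprod(Vk, h_probk)) / n
  if (!all(is.finite(dW))) stop_dtcn("non-finite CD update")
  rbm$W <- rbm$W + lr * dW
  rbm$b_vis <- rbm$b_vis + lr * colMeans(V0 - Vk)
  rbm$b_hid <- rbm$b_hid + lr * colMeans(h_prob0 - h_probk)
  list(rbm = rbm, recon_error = mean((V0 - Vk)^2))
}

#' Greedy pretraining of a DTCN as a stack of RBMs
#'
#' Trains the network's connections pair-wise and unsupervised, bottom-up.
#' Connection 1 is pretrained as a gaussian-visible RBM between the
#' standardized input and the first hidden layer.  Each deeper connection
#' `i > 1` is pretrained as a bernoulli-visible RBM whose visible layer is
#' the concatenation sublayer of layer `i - 1`: hidden probabilities are
#' propagated (mean-field, no sampling) through the already-trained stack,
#' concatenated with `TS`, and fed to the next RBM.  The softmax connection
#' is not pretrained (pretraining involves neither the softmax layer nor
#' the labels).  Trained weights and hidden biases are transferred into the
#' returned parameters; fine-tuning then starts from them.
#'
#' @param params a [dtcn_params()] giving the architecture.
#' @param batches list of standardized training mini-batches.
#' @param config list: `epochs` (default 10), `lr` (default 0.05), `k`
#'   (Gibbs steps, default 1), `seed` (default 1).
#' @return `params` with pretrained weights/biases for all hidden
#'   connections, with attribute `"recon_errors"` (per-connection vector of
#'   final-epoch mean reconstruction errors).
#' @export
pretrain_stack <- function(params, batches, config = list()) {
  stopifnot(inherits(params, "dtcn_params"))
  epochs <- if (is.null(config$epochs)) 10L else as.integer(config$epochs)
  lr <- if (is.null(config$lr)) 0.05 else config$lr
  k <- if (is.null(config$k)) 1L else as.integer(config$k)
  seed <- if (is.null(config$seed)) 1L else config$seed
  sizes <- params$layer_sizes
  L <- length(sizes) - 2L
  ts <- params$ts
  ## visible data per batch, labels never passed along
  vis <- lapply(batches, function(b)
    if (inherits(b, "minibatch")) b$features else as.matrix(b))
  final_err <- numeric(L)
  for (i in seq_len(L)) {
    vtype <- if (i == 1L) "gaussian" else "bernoulli"
    rbm <- rbm_init(nrow(params$W[[i]]), sizes[i + 1L],
                    visible_type = vtype, seed = derive_seed(seed, 100L + i))
    rng <- rng_stream(derive_seed(seed, 200L + i))
    for (e in seq_len(epochs)) {
      errs <- numeric(length(vis))
      for (bi in seq_along(vis)) {
        res <- cd_step(rbm, vis[[bi]], k = k, lr = lr, rng = rng)
        rbm <- res$rbm
        errs[bi] <- res$recon_error
      }
      final_err[i] <- mean(errs)
    }
    params$W[[i]] <- rbm$W
    params$b[[i]] <- rbm$b_hid
    if (i < L) {
      vis <- lapply(vis, function(v) {
        if (nrow(v) < ts)
          stop_dtcn("batch too small for concatenation during pretraining")
        h <- sigmoid(add_rows(v %*% rbm$W, rbm$b_hid))
        concat_rows(h, ts)
      })
    }
  }
  attr(params, "recon_errors") <- final_err
  params
}
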