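#' Specification of a synthetic regime-switching signal
#'
#' Describes a nonstationary multichannel series whose per-sample class
#' label follows a slowly switching latent Markov state: each class drives
#' a distinct quasi-oscillatory AR(2) regime in every channel, so the
#' discriminative information is spectral and spans temporal context well
#' beyond a single sample — the structure a temporal-context classifier is
#' built to exploit.
#'
#' @param n_channels number of channels `C`.
#' @param n_samples series length `N`.
#' @param n_classes number of latent classes `K >= 2`.
#' @param mean_dwell expected number of samples between latent switches
#'   (dwell times are geometric, i.e. switching is memoryless).
#' @param snr linear signal-to-noise ratio (signal power over additive
#'   white-noise power).
#' @param seed seed; the generated record is fully determined by it.
#' @return Object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_channels = 6L, n_samples = 10000L, n_classes = 2L,
                       mean_dwell = 300, snr = 4, seed = 1L) {
  spec <- list(n_channels = as.integer(n_channels),
               n_samples = as.integer(n_samples),
               n_classes = as.integer(n_classes),
               mean_dwell = mean_dwell, snr = snr, seed = as.integer(seed))
  if (spec$n_channels < 1L || spec$n_samples < 1L)
    stop_dtcn("need at least one channel and one sample")
  if (spec$n_classes < 2L) stop_dtcn("'n_classes' must be >= 2")
  if (spec$mean_dwell < 1) stop_dtcn("'mean_dwell' must be >= 1")
  if (spec$snr <= 0) stop_dtcn("'snr' must be positive")
  structure(spec, class = "synth_spec")
}

#' Generate a synthetic labelled regime-switching series
#'
#' The latent class sequence is a `K`-state Markov chain with stay
#' probability `1 - 1/mean_dwell` (geometric dwell times of mean
#' `mean_dwell`) and uniform jumps among the other states.  Class `k` maps,
#' in each channel, to an AR(2) regime with a distinct dominant frequency
#' (complex poles at radius 0.95); regime coefficients are blended linearly
#' over 5 samples after each switch to avoid discontinuities.  Channels are
#' scaled to unit power and white Gaussian noise with power `1/snr` is
#' added.  Labels are the latent state per sample.
#'
#' @param spec a [synth_spec()].
#' @return A [ts_record()].
#' @examples
#' rec <- generate_series(synth_spec(n_samples = 2000, seed = 7))
#' table(rec$labels)
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  N <- spec$n_samples; C <- spec$n_channels; K <- spec$n_classes
  rng <- rng_stream(spec$seed)

  ## latent Markov chain, vectorised: switch indicators + uniform jumps
  p_switch <- 1 / spec$mean_dwell
  states <- rng$draw(function() {
    s0 <- sample.int(K, 1L) - 1L
    sw <- stats::runif(N - 1L) < p_switch
    jump <- sample.int(K - 1L, N - 1L, replace = TRUE)
    c(s0, (s0 + cumsum(ifelse(sw, jump, 0L))) %% K)
  })

  ## per class x channel AR(2) regimes: distinct dominant frequencies
  ## spread over [0.10, 0.35] cycles/sample (periods of 3-10 samples, so
  ## every class's oscillation is visible inside short analysis windows),
  ## with small per-channel offsets
  base_f <- 0.10 + 0.25 * (seq_len(K) - 1L) / max(K - 1L, 1L)
  jitter <- rng$draw(function() matrix(stats::runif(K * C, 0, 0.02), K, C))
  freq <- outer(base_f, rep(1, C)) + jitter
  r <- 0.95
  a1 <- 2 * r * cospi(2 * freq)               # K x C
  a2 <- matrix(-r^2, K, C)

  ## blend regime coefficients over 5 samples after each switch
  wts <- matrix(0, N, K)
  wts[cbind(seq_len(N), states + 1L)] <- 1
  if (N >= 5L) {
    sm <- apply(wts, 2L, function(col)
      as.numeric(stats::filter(col, rep(1 / 5, 5), sides = 1L)))
    sm[seq_len(4L), ] <- wts[seq_len(4L), ]
    wts <- sm / rowSums(sm)
  }
  A1 <- wts %*% a1                             # N x C, per-sample coefficients
  A2 <- wts %*% a2

  innov <- rng$draw(function() matrix(stats::rnorm(N * C), N, C))
  x <- matrix(0, N, C)
  if (N >= 1L) x[1L, ] <- innov[1L, ]
  if (N >= 2L) x[2L, ] <- A1[2L, ] * x[1L, ] + innov[2L, ]
  for (t in seq_len(N)[-(1:2)])
    x[t, ] <- A1[t, ] * x[t - 1L, ] + A2[t, ] * x[t - 2L, ] + innov[t, ]

  ## unit signal power per channel, then class-dependent channel gain and
  ## baseline offset (amplitude and DC shifts accompany spectral regime
  ## changes in physiological recordings), blended with the same smoothing
  pow <- sqrt(colMeans(x^2))
  pow[pow == 0] <- 1
  x <- sweep(x, 2L, pow, "/")
  gain <- rng$draw(function() matrix(stats::runif(K * C, 0.6, 1.4), K, C))
  offset <- rng$draw(function() matrix(stats::runif(K * C, -0.4, 0.4), K, C))
  x <- x * (wts %*% gain) + wts %*% offset
  noise <- rng$draw(function()
    matrix(stats::rnorm(N * C, sd = 1 / sqrt(spec$snr)), N, C))
  ts_record(x + noise, states, n_classes = K)
}
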