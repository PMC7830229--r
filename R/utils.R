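#' @keywords internal
"_PACKAGE"

## Independent, resumable RNG streams.  Tie-breaking, mini-batch shuffling,
## weight initialisation and CD sampling each own a stream seeded from the
## user's master seed, so consuming one never perturbs another (or the
## caller's RNG).

rng_stream <- function(seed) {
  seed <- as.integer(seed)
  state <- NULL
  draw <- function(fn) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (has_old) assign(".Random.seed", old, envir = globalenv()) else
        rm(".Random.seed", envir = globalenv())
    })
    fn()
  }
  structure(list(draw = draw, seed = seed), class = "dtcn_rng")
}

## Derive child seeds from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(y) {
  y <- y - apply(y, 1L, max)          # max-subtraction for overflow safety
  e <- exp(y)
  e / rowSums(e)
}

## Sweep a vector over matrix rows (add bias / scale features).
add_rows <- function(m, v) sweep(m, 2L, v, "+")

stop_dtcn <- function(...) stop(sprintf(...), call. = FALSE)
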