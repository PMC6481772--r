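# Reproducible sub-stream seeding.  Every stochastic operation in the
# package derives its own seed from (user seed, stream name) so that each
# step is independently replayable and no operation perturbs the caller's
# RNG state.

.stream_ids <- c(
  spectra     = 101L,
  abundances  = 211L,
  noise       = 307L,
  sketch      = 401L,
  krylov      = 503L,
  misc        = 601L
)

#' Derive a sub-seed for a named random stream
#'
#' Maps a user-level integer seed plus a stream label to a deterministic
#' 31-bit seed, so independent operations (spectra, abundances, noise,
#' random sketches) never share an RNG stream.
#'
#' @param seed integer master seed.
#' @param stream one of `"spectra"`, `"abundances"`, `"noise"`,
#'   `"sketch"`, `"krylov"`, `"misc"`.
#' @param counter optional non-negative integer to split a stream further
#'   (e.g. per retry or per repetition).
#' @return an integer seed in `[0, 2^31)`.
#' @export
split_seed <- function(seed, stream = "misc", counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  id <- .stream_ids[[match.arg(stream, names(.stream_ids))]]
  # 64-bit-safe mixing in double arithmetic, reduced mod 2^31 - 1
  m <- 2147483647
  x <- (abs(seed) %% m)
  x <- (x * 48271) %% m
  x <- (x + id * 69621 + counter * 16807) %% m
  as.integer(x)
}

# Run `code` under a fixed seed, restoring the global RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
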