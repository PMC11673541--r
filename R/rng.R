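#' Named random-number substreams
#'
#' A run seeds one master stream and splits it into independent named
#' substreams (e.g. "scenario", "migration", "branching").  Each substream
#' carries its own `.Random.seed` state, so draws in one stream never perturb
#' another: adding a new consumer of randomness leaves existing trajectories
#' bit-identical.
#'
#' @param seed integer master seed (kept below 2^31).
#' @param streams character vector of substream names.
#' @return an object of class `rng_streams`.
#' @export
rng_streams <- function(seed, streams = c("scenario", "migration", "branching")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed %% .Machine$integer.max)
  env <- new.env(parent = emptyenv())
  # derive per-stream seeds deterministically from the master seed
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(streams))
  for (i in seq_along(streams)) {
    set.seed(sub_seeds[i])
    assign(streams[i], get(".Random.seed", globalenv()), envir = env)
  }
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(states = env, seed = seed), class = "rng_streams")
}

#' Evaluate an expression under a named substream
#'
#' Swaps the substream's RNG state into the session, evaluates `fn`, then
#' captures the advanced state back into the substream and restores the
#' session state.
#'
#' @param rng an `rng_streams` object.
#' @param stream substream name.
#' @param fn a function of no arguments performing the random draws.
#' @return the value of `fn()`.
#' @export
with_stream <- function(rng, stream, fn) {
  stopifnot(inherits(rng, "rng_streams"))
  if (!exists(stream, envir = rng$states, inherits = FALSE))
    stop("unknown RNG substream: ", stream)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", get(stream, envir = rng$states), envir = globalenv())
  on.exit({
    assign(stream, get(".Random.seed", globalenv()), envir = rng$states)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  fn()
}
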