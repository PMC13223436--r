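# Seed plumbing: one user-facing seed expands into named substreams so that
# data generation, weight init, augmentation and the dropout search draw from
# independent, order-insensitive streams.

#' Derive a substream seed from a base seed and a set of tags
#'
#' Hashes the base seed together with integer or character tags into a
#' deterministic 31-bit seed.  Used throughout the package to give every
#' image, fold and optimizer round its own reproducible RNG stream.
#'
#' @param ... integers or strings; the first element is conventionally the
#'   base seed.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
hash_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) as.integer(unlist(lapply(p, utf8ToInt))) else as.integer(p)
  }), use.names = FALSE)
  if (any(is.na(parts))) stop("hash_seed: non-integer, non-character tag")
  h <- 5381
  for (k in parts) {
    h <- (h * 33 + (k %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, and restores, so library
#' internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# dimension-preserving clamps
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
clip_to <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}
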