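# Deterministic substream seeding.
#
# All stochastic generators in the package draw from substreams derived by
# stable hashing of a root seed plus string labels (condition, protein id,
# interval coordinates, replicate index, ...). This guarantees that adding
# a protein to a proteome, or a condition to an experiment, never perturbs
# the random draws of the others, and that quantities keyed to the same
# labels (e.g. peptide detectability) agree exactly across conditions.

#' Derive a reproducible substream seed from a root seed and labels
#'
#' Hashes the root seed together with an arbitrary set of string labels into
#' a positive 31-bit integer suitable for `set.seed()`. The hash is a
#' polynomial string hash over the UTF-8 bytes of the concatenated labels,
#' followed by three multiplicative (Lehmer, MINSTD) scrambling steps, all
#' carried out exactly in double-precision arithmetic modulo the Mersenne
#' prime 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param ... Labels (coerced to character) identifying the substream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1L, "pronase", "P0007")
substream_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  labels <- paste(vapply(list(...), as.character, character(1)),
                  collapse = "\x1f")
  h <- (abs(as.numeric(seed)) + 1) %% m
  for (b in utf8ToInt(labels)) {
    h <- (h * 31 + b) %% m
  }
  # Lehmer scrambles: products stay below 2^53, so exact in doubles.
  for (i in 1:3) h <- (h * 48271) %% m
  if (h == 0) h <- 1
  as.integer(h)
}

#' Deterministic uniform deviate keyed to labels
#'
#' Returns a single uniform (0,1) value that depends only on the root seed
#' and the labels, independent of R's global RNG state. Used where a random
#' decision must be reproducible across contexts that share the same key
#' (e.g. peptide detectability shared between experimental conditions).
#'
#' @inheritParams substream_seed
#' @return A double in (0, 1).
#' @keywords internal
hash_uniform <- function(seed, ...) {
  substream_seed(seed, ...) / 2147483647
}

# Run an expression under a local, seeded RNG without touching the caller's
# RNG state.
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
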