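# Shared helpers: seed derivation, deterministic string hashing, RNG scoping.

#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Stage- and
#' epoch-level seeds are derived deterministically so that independent
#' stages draw from decoupled streams while the whole pipeline stays
#' reproducible. Results stay below 2^31 so they are valid R integers.
#'
#' @param seed Integer root seed.
#' @param ... Integers or strings identifying the consumer (stage, epoch).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  salt <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(salt)) h <- (h * 131 + cp) %% 2147483629
  as.integer(h)
}

# evaluate expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic string hash onto 1..nbits (used for hashed fingerprints);
# implemented in-package so fingerprints are stable across sessions and
# library versions
hash_to_bit <- function(s, nbits) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483629
  (h %% nbits) + 1L
}

# (i, j, x) triplets of a sparse matrix in general storage: symmetric or
# triangular classes would otherwise report one triangle only
.sparse_triplets <- function(m) {
  m <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  data.frame(i = m@i + 1L, j = m@j + 1L, x = m@x)
}

# choose exactly round(rate * n) items; count-based so realized rates are
# exact and assertions deterministic
sample_exact <- function(n, rate) {
  k <- round(rate * n)
  if (k <= 0L) return(integer(0))
  sample.int(n, k)
}
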