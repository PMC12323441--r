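## Internal helpers shared across modules.

## Run `code` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so that seeded package functions do not perturb the
## user's random stream.  `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

## Spawn `n` independent substream seeds from one master seed.  Each
## substream is an ordinary 32-bit integer seed, so replicates are
## individually reproducible.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

is_square_symmetric <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) && is.numeric(x) &&
    max(abs(x - t(x))) <= tol
}

## All unordered variable pairs of 1..p as a 2-column matrix (i < j).
all_pairs <- function(p) {
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
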