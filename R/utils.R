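# internal helpers shared across modules

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

# row-wise Euclidean normalization of an n x 3 matrix
unitize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stopf("zero-length 3-vector cannot be normalized")
  m / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
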