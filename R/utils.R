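#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing used everywhere the package needs several
#' independent random streams from one master seed (data simulation, per-start
#' ECM randomization, bootstrap replicates).  Results stay inside the 32-bit
#' integer range R requires of `set.seed`.
#'
#' @param seed master seed (single integer) or `NULL` for no seeding.
#' @param ... one or more non-negative integer stream indices.
#' @return a single integer seed, or `NULL` if `seed` is `NULL`.
#' @export
deriveSeed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 7919 + 1) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards.  seed = NULL => no-op.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# canonical name for a population pair
pairKey <- function(a, b) paste(a, b, sep = "|")

`%||%` <- function(a, b) if (is.null(a)) b else a
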