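#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois runif rnorm dpois ppois pchisq lm coef vcov setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Run `expr` under a temporary Mersenne-Twister RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.  All randomized operations in the
# package route through this so results are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Derive a per-frame substream seed from a base seed; keeps every regeneration
# of a dot cloud (e.g. after a zoom change) reproducible yet distinct.
frame_seed <- function(seed, frame = 0L) {
  as.integer((as.double(seed) + 9973 * as.double(frame)) %% 2147483647)
}

vnorm <- function(x) sqrt(sum(x^2))

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
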