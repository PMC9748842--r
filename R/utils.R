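# Internal helpers: seeding, RNG scoping, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed and stream indices
#'
#' All randomness in the package flows from one integer seed; substreams
#' (per phantom, per epoch, per augmentation) are derived with this mixing
#' function so that corpus generation, training and evaluation are
#' reproducible file-for-file. Result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed integer parent seed.
#' @param ... further integer stream indices.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + (as.numeric(k) %% 2147483629) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
# `seed = NULL` evaluates in the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# clamp a numeric vector to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
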