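# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library functions can be
#' deterministic without clobbering the global stream. A `NULL` seed leaves
#' the current stream untouched.
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and an index.
# Arithmetic in double to avoid 32-bit overflow.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_aztair <- function(...) stop(..., call. = FALSE)

# Dirichlet draw via independent gammas; rows are draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  sw <- rowSums(x)
  # guard against an all-zero row when every alpha is minuscule
  zero <- sw == 0
  if (any(zero)) {
    x[zero, ] <- 1 / k
    sw[zero] <- 1
  }
  x / sw
}
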