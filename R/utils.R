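# Internal helpers shared across modules.

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library code never clobbers a user's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

#' Derive a deterministic sub-seed
#'
#' Hashes a master seed together with an integer stream index (for example
#' the cluster count `k` in a sweep) into a new seed, so that adding or
#' removing streams never perturbs the draws of the others. The result is
#' always a valid 32-bit R seed.
#'
#' @param seed Integer master seed.
#' @param index Integer stream index (>= 0).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  # Knuth multiplicative hash; doubles hold the product exactly (< 2^53).
  m <- 2147483647
  h <- ((seed %% m) * 2654435761) %% m
  h <- (h + (index %% m) * 40503 + 17) %% m
  as.integer(h)
}

stop_traj <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Squared Euclidean distances between rows of x (n x d) and rows of
# centers (k x d); returns n x k matrix.
sq_dist_to_centers <- function(x, centers) {
  n2x <- rowSums(x^2)
  n2c <- rowSums(centers^2)
  d2 <- outer(n2x, n2c, "+") - 2 * tcrossprod(x, centers)
  # guard tiny negatives from floating point
  d2[d2 < 0] <- 0
  d2
}
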