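# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores whatever `.Random.seed`
#' was in place before, so seeded operations stay pure functions of their
#' inputs and never disturb the caller's RNG stream.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a user seed, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 7919) %% 2147483629
}

# Euclidean distances from one point (length-3) to rows of a n x 3 matrix.
dist_to_points <- function(p, pts) {
  sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2)
}

# Pairwise Euclidean distances between rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
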