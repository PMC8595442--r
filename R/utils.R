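# Internal helpers shared across the package.

#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so that seeded simulators are reproducible without clobbering the
#' global stream. `seed = NULL` uses (and advances) the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct child seed from a parent seed (kept inside 32-bit range;
# double arithmetic avoids integer overflow for large parents).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 31 + as.numeric(k)) %% 2147483587
}

# Symmetric matrix square root via eigendecomposition; X must be PSD.
mat_sqrt <- function(X) {
  e <- eigen((X + t(X)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Solve Gamma %*% x = b with a small ridge for conditioning.
# ridge is relative: lambda = ridge * trace(Gamma) / ncol(Gamma).
ridge_solve <- function(Gamma, b, ridge = 1e-6) {
  d <- ncol(Gamma)
  lambda <- ridge * sum(diag(Gamma)) / d
  G <- Gamma + diag(lambda, d)
  out <- try(solve(G, b), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("feature covariance is singular; increase `ridge`", call. = FALSE)
  out
}

# Multivariate normal draws: n x d matrix with mean mu and covariance Sigma.
rmvn <- function(n, mu, Sigma) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% mat_sqrt(Sigma), 2, mu, "+")
}

# Random positive-definite covariance with moderate condition number,
# used by tests and simulations of abstract feature models.
random_pd_matrix <- function(d, spread = 2) {
  A <- matrix(stats::rnorm(d * d), d, d)
  Q <- qr.Q(qr(A))
  vals <- exp(stats::runif(d, -log(spread), log(spread)))
  Q %*% (vals * t(Q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
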