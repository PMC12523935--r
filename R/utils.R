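#' @importFrom rlang %||% .data
#' @importFrom stats setNames
#' @keywords internal
"_PACKAGE"

# Row-wise log-sum-exp of a matrix, numerically stable.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Multivariate normal log-density via Cholesky; x is n x d, sigma d x d.
dmvnorm_log <- function(x, mean, sigma) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  d <- length(mean)
  U <- chol(sigma)
  xc <- sweep(x, 2, mean)
  w <- backsolve(U, t(xc), transpose = TRUE)
  maha <- colSums(w^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + maha)
}

# Draw n samples from N(mean, sigma) given a fixed RNG state.
rmvnorm_chol <- function(n, mean, sigma) {
  d <- length(mean)
  U <- chol(sigma)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% U, 2, mean, `+`)
}

#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own 32-bit seed from the
#' master seed and a stage label, so that e.g. changing bootstrap settings
#' never perturbs cohort generation.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage ("cohort", "mortality", ...).
#' @return an integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

# Check a matrix is symmetric positive definite; returns TRUE/FALSE.
is_spd <- function(m, tol = 1e-10) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}
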