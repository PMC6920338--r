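# Independent dense-matrix oracles used to validate the fast implementations.
# These deliberately avoid the eigen-rotation and partitioned-solve paths.

# Profiled restricted log likelihood evaluated with dense solves, same
# additive-constant convention as the package (no 2*pi term).
dense_restricted_loglik <- function(lambda, y, K, X) {
  n <- length(y)
  q <- ncol(X)
  V0 <- unclass(K) * lambda + diag(n)
  Vi <- solve(V0)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - q)
  V <- V0 * s2
  ViS <- solve(V)
  drop(-0.5 * determinant(V, logarithm = TRUE)$modulus[1] -
    0.5 * determinant(t(X) %*% ViS %*% X, logarithm = TRUE)$modulus[1] -
    0.5 * t(r) %*% ViS %*% r)
}

# BLUP of the test set by a direct dense solve of the partitioned equations
dense_blup <- function(lambda, beta, y1, X1, K11, K21, X2) {
  drop(X2 %*% beta) +
    lambda * drop(K21 %*% solve(unclass(K11) * lambda + diag(length(y1)),
                                y1 - drop(X1 %*% beta)))
}

# Kinship by an explicit loop over markers (sum of outer products / m)
brute_kinship <- function(Z) {
  n <- ncol(Z)
  K <- matrix(0, n, n)
  for (k in seq_len(nrow(Z))) {
    K <- K + tcrossprod(Z[k, ])
  }
  K / nrow(Z)
}

# Fine grid search maximizer of the restricted likelihood over log lambda,
# refined by golden-section; independent of the Newton path.
grid_search_lambda <- function(y, K, X = NULL, lo = 1e-6, hi = 1e6) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  eig <- eigendecompose(K)
  f <- function(th) restricted_loglik(exp(th), y, X = X, eig = eig)
  grid <- seq(log(lo), log(hi), length.out = 200)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo_i <- grid[max(1, i - 1)]
  hi_i <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, interval = c(lo_i, hi_i), maximum = TRUE,
                         tol = 1e-12)
  exp(opt$maximum)
}

# Random genotype panel + phenotype with polygenic signal
rand_instance <- function(n, m, lambda = 1, seed = 1, q_extra = 0) {
  withr::with_seed(seed, {
    Z <- matrix(sample(c(-1, 0, 1), m * n, replace = TRUE,
                       prob = c(0.4, 0.2, 0.4)), m, n)
    K <- compute_kinship(genotype_matrix(Z))
    g <- drop(crossprod(Z, stats::rnorm(m, 0, sqrt(lambda / m))))
    y <- g + stats::rnorm(n)
    X <- matrix(1, n, 1)
    if (q_extra > 0) X <- cbind(X, matrix(stats::rnorm(n * q_extra), n))
    list(Z = Z, K = K, y = y, X = X)
  })
}
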