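# Multi-kernel REML: additive + dominance, and genotype-by-environment.
# These models have two variance ratios, so the single-kernel eigen trick no
# longer diagonalises the covariance; the profiled restricted likelihood is
# evaluated densely through a Cholesky factorisation of
# V0 = sum_k K_k lambda_k + I.

# Profiled restricted log likelihood for V = V0 * sigma^2, same constant
# convention as reml_parts().
dense_profiled_loglik <- function(V0, y, X) {
  n <- length(y)
  q <- ncol(X)
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  ldV0 <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  A <- crossprod(X, Vi_X)
  Ai <- tryCatch(solve(A), error = function(e) pseudo_inverse(A))
  beta <- drop(Ai %*% crossprod(Vi_X, y))
  r <- y - drop(X %*% beta)
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  S <- sum(r * Vi_r)
  sigma2 <- S / (n - q)
  ldA <- determinant(A, logarithm = TRUE)$modulus[1]
  list(loglik = -0.5 * ldV0 - 0.5 * ldA - (n - q) / 2 * log(sigma2) -
         (n - q) / 2,
       beta = beta, sigma2 = sigma2)
}

#' Restricted log likelihood of the additive-plus-dominance model
#'
#' Profiled REML log likelihood of the two-kernel model with covariance
#' V = (K lambda_A + K_D lambda_D + I) sigma^2, with fixed effects and
#' sigma^2 absorbed as in [restricted_loglik()] (same additive-constant
#' convention).
#'
#' @param lambda_a,lambda_d Non-negative variance ratios for the additive and
#'   dominance kernels.
#' @param y Phenotype vector.
#' @param K,K_D Additive and dominance kinship matrices.
#' @param X Fixed-effect design (default intercept).
#' @return Scalar log likelihood.
#' @export
ad_restricted_loglik <- function(lambda_a, lambda_d, y, K, K_D, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  V0 <- as_kinship(K) * lambda_a + as_kinship(K_D) * lambda_d +
    diag(length(y))
  dense_profiled_loglik(V0, y, as.matrix(X))$loglik
}

#' Fit the additive-plus-dominance (A-D) GBLUP model
#'
#' Extends the additive model with a dominance kernel built from
#' heterozygosity codes (see [compute_dominance_kinship()]):
#' V = (K lambda_A + K_D lambda_D + I) sigma^2. The two ratios are estimated
#' by REML, maximising over (log lambda_A, log lambda_D) with a Nelder-Mead
#' start polished by quasi-Newton (BFGS). A dominance kernel that is
#' identically zero carries no information about lambda_D; the model then
#' degenerates to the additive model and the additive fit is returned with
#' lambda_D = 0.
#'
#' @param y Phenotype vector.
#' @param K Additive kinship matrix.
#' @param K_D Dominance kinship matrix of the same dimension.
#' @param X Fixed-effect design (default intercept).
#' @return An object of class `reml_fit_ad` with `lambda_a`, `lambda_d`,
#'   `beta_hat`, `sigma2_hat`, `phi2_a`, `phi2_d`, `restricted_loglik`,
#'   `converged`, and the training data needed by [blup_predict_ad()].
#' @export
fit_ad_model <- function(y, K, K_D, X = NULL) {
  K <- as_kinship(K)
  K_D <- as_kinship(K_D)
  y <- as.numeric(y)
  if (!all(dim(K) == dim(K_D))) {
    stop("K and K_D must have the same dimension.", call. = FALSE)
  }
  if (is.null(X)) X <- matrix(1, length(y), 1)
  X <- as.matrix(X)
  if (max(abs(K_D)) == 0) {
    add <- fit_reml(y, K, X)
    out <- list(lambda_a = add$lambda_hat, lambda_d = 0,
                beta_hat = add$beta_hat, sigma2_hat = add$sigma2_hat,
                phi2_a = add$phi2_hat, phi2_d = 0,
                restricted_loglik = add$restricted_loglik,
                converged = add$converged, n = add$n, q = add$q,
                y = add$y, X = add$X, K = K, K_D = K_D)
    return(structure(out, class = "reml_fit_ad"))
  }
  n <- length(y)
  In <- diag(n)
  obj <- function(th) {
    lam <- exp(pmin(th, 25))
    -dense_profiled_loglik(K * lam[1] + K_D * lam[2] + In, y, X)$loglik
  }
  nm <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
  bf <- tryCatch(stats::optim(nm$par, obj, method = "BFGS",
                              control = list(maxit = 200, reltol = 1e-14)),
                 error = function(e) nm)
  best <- if (bf$value <= nm$value) bf else nm
  lam <- exp(best$par)
  lam[lam < 1e-7] <- 0
  fin <- dense_profiled_loglik(K * lam[1] + K_D * lam[2] + In, y, X)
  structure(list(
    lambda_a = lam[1], lambda_d = lam[2],
    beta_hat = fin$beta, sigma2_hat = fin$sigma2,
    phi2_a = lam[1] * fin$sigma2, phi2_d = lam[2] * fin$sigma2,
    restricted_loglik = fin$loglik,
    converged = best$convergence == 0,
    n = n, q = ncol(X), y = y, X = X, K = K, K_D = K_D
  ), class = "reml_fit_ad")
}

#' @export
print.reml_fit_ad <- function(x, ...) {
  cat("<reml_fit_ad> additive + dominance GBLUP\n")
  cat(sprintf("  lambda_A: %.6g  lambda_D: %.6g  sigma2: %.6g\n",
              x$lambda_a, x$lambda_d, x$sigma2_hat))
  cat(sprintf("  restricted logLik: %.6g\n", x$restricted_loglik))
  invisible(x)
}

#' BLUP prediction under the A-D model
#'
#' y2-hat = X2 beta-hat + (lambda_A K21 + lambda_D K_D21)
#'   (K11 lambda_A + K_D11 lambda_D + I)^-1 (y1 - X1 beta-hat).
#'
#' @param fit A `reml_fit_ad` from [fit_ad_model()].
#' @param K21,KD21 Test-by-training blocks of the additive and dominance
#'   kinship matrices.
#' @param X2 Test fixed-effect design (default intercepts).
#' @param hybrid_ids Optional test ids (default: rownames of `K21`).
#' @return A tibble with `hybrid_id` and `y_hat`.
#' @export
blup_predict_ad <- function(fit, K21, KD21, X2 = NULL, hybrid_ids = NULL) {
  stopifnot(inherits(fit, "reml_fit_ad"))
  K21 <- as.matrix(K21); KD21 <- as.matrix(KD21)
  n1 <- length(fit$y)
  stopifnot(ncol(K21) == n1, all(dim(K21) == dim(KD21)))
  n2 <- nrow(K21)
  if (is.null(X2)) X2 <- matrix(1, n2, ncol(fit$X))
  ids <- hybrid_ids %||% rownames(K21) %||% paste0("hyb", seq_len(n2))
  V011 <- fit$K * fit$lambda_a + fit$K_D * fit$lambda_d + diag(n1)
  resid <- fit$y - drop(fit$X %*% fit$beta_hat)
  adj <- solve(V011, resid)
  y_hat <- drop(as.matrix(X2) %*% fit$beta_hat) +
    drop((fit$lambda_a * K21 + fit$lambda_d * KD21) %*% adj)
  tibble::tibble(hybrid_id = as.character(ids), y_hat = y_hat)
}

#' Restricted log likelihood of the G x E model
#'
#' Profiled REML log likelihood of the stacked multi-environment model (see
#' [fit_gxe_model()]) at given ratios, evaluated densely over the nE x nE
#' covariance.
#'
#' @param lambda_main,lambda_gxe Non-negative ratios for the genomic main
#'   effect and the genotype-by-environment deviation.
#' @param Y n x E phenotype matrix (hybrids x environments).
#' @param K Kinship matrix of the n hybrids.
#' @return Scalar log likelihood.
#' @export
gxe_restricted_loglik <- function(lambda_main, lambda_gxe, Y, K) {
  st <- gxe_stack(Y, as_kinship(K))
  dense_profiled_loglik(
    st$KJ * lambda_main + st$KI * lambda_gxe + diag(length(st$y)),
    st$y, st$X)$loglik
}

gxe_stack <- function(Y, K) {
  Y <- as.matrix(Y)
  n <- nrow(Y); E <- ncol(Y)
  stopifnot(nrow(K) == n)
  JE <- matrix(1, E, E)
  list(y = as.vector(Y),                         # env-major stacking
       X = kronecker(diag(E), matrix(1, n, 1)),  # environment means
       KJ = kronecker(JE, K),                    # shared genomic effect
       KI = kronecker(diag(E), K),               # env-specific deviation
       n = n, E = E)
}

#' Fit the genotype-by-environment (G x E) GBLUP model
#'
#' Observations from E environments on the same n hybrids are stacked into a
#' single vector of length nE with environment-specific fixed means. The
#' genetic covariance has a main genomic effect shared across environments,
#' cov = (J_E \%x\% K) phi2_main with J_E the all-ones E x E matrix, plus an
#' interaction deviation independent across environments,
#' (I_E \%x\% K) phi2_gxe (a linear-kernel multi-environment GBLUP).
#' REML maximises over the two ratios as in [fit_ad_model()]. With a single
#' environment the interaction is not identifiable and the additive fit is
#' returned with lambda_gxe = 0.
#'
#' @param Y n x E phenotype matrix, one column per environment (colnames used
#'   as environment labels), rows aligned with `K`.
#' @param K Kinship matrix of the n hybrids.
#' @return An object of class `reml_fit_gxe` with `lambda_main`,
#'   `lambda_gxe`, per-environment fixed means `beta_hat`, `sigma2_hat`,
#'   `restricted_loglik`, `converged`, and training data for
#'   [blup_predict_gxe()].
#' @export
fit_gxe_model <- function(Y, K) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("phenotype matrix must be complete.", call. = FALSE)
  K <- as_kinship(K)
  if (nrow(Y) != nrow(K)) {
    stop("rows of Y must match the kinship matrix.", call. = FALSE)
  }
  E <- ncol(Y)
  envs <- colnames(Y) %||% paste0("env", seq_len(E))
  if (E < 1) stop("need at least one environment.", call. = FALSE)
  if (E == 1) {
    add <- fit_reml(drop(Y), K)
    out <- list(lambda_main = add$lambda_hat, lambda_gxe = 0,
                beta_hat = stats::setNames(add$beta_hat, envs),
                sigma2_hat = add$sigma2_hat,
                phi2_main = add$phi2_hat, phi2_gxe = 0,
                restricted_loglik = add$restricted_loglik,
                converged = add$converged,
                Y = Y, K = K, envs = envs)
    return(structure(out, class = "reml_fit_gxe"))
  }
  st <- gxe_stack(Y, K)
  In <- diag(length(st$y))
  obj <- function(th) {
    lam <- exp(pmin(th, 25))
    -dense_profiled_loglik(st$KJ * lam[1] + st$KI * lam[2] + In,
                           st$y, st$X)$loglik
  }
  nm <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
  bf <- tryCatch(stats::optim(nm$par, obj, method = "BFGS",
                              control = list(maxit = 200, reltol = 1e-14)),
                 error = function(e) nm)
  best <- if (bf$value <= nm$value) bf else nm
  lam <- exp(best$par)
  lam[lam < 1e-7] <- 0
  fin <- dense_profiled_loglik(st$KJ * lam[1] + st$KI * lam[2] + In,
                               st$y, st$X)
  structure(list(
    lambda_main = lam[1], lambda_gxe = lam[2],
    beta_hat = stats::setNames(fin$beta, envs),
    sigma2_hat = fin$sigma2,
    phi2_main = lam[1] * fin$sigma2, phi2_gxe = lam[2] * fin$sigma2,
    restricted_loglik = fin$loglik,
    converged = best$convergence == 0,
    Y = Y, K = K, envs = envs
  ), class = "reml_fit_gxe")
}

#' @export
print.reml_fit_gxe <- function(x, ...) {
  cat(sprintf("<reml_fit_gxe> %d environment(s)\n", length(x$envs)))
  cat(sprintf("  lambda_main: %.6g  lambda_gxe: %.6g  sigma2: %.6g\n",
              x$lambda_main, x$lambda_gxe, x$sigma2_hat))
  cat(sprintf("  restricted logLik: %.6g\n", x$restricted_loglik))
  invisible(x)
}

#' Per-environment BLUP prediction under the G x E model
#'
#' For test hybrids with kinship block K21 to the training hybrids, the
#' prediction in environment e combines the shared genomic effect and the
#' environment-specific deviation: the covariance between a test genetic
#' value in environment e and the training observation in environment f is
#' K21 (lambda_main + lambda_gxe [e == f]) sigma^2.
#'
#' @param fit A `reml_fit_gxe` from [fit_gxe_model()].
#' @param K21 Test-by-training kinship block (n2 x n1).
#' @param hybrid_ids Optional test ids (default: rownames of `K21`).
#' @return A tibble with `hybrid_id`, `environment`, `y_hat`.
#' @export
blup_predict_gxe <- function(fit, K21, hybrid_ids = NULL) {
  stopifnot(inherits(fit, "reml_fit_gxe"))
  K21 <- as.matrix(K21)
  n1 <- nrow(fit$K)
  stopifnot(ncol(K21) == n1)
  n2 <- nrow(K21)
  E <- length(fit$envs)
  ids <- hybrid_ids %||% rownames(K21) %||% paste0("hyb", seq_len(n2))
  if (E == 1) {
    resid <- drop(fit$Y) - fit$beta_hat[1]
    adj <- solve(fit$K * fit$lambda_main + diag(n1), resid)
    y_hat <- fit$beta_hat[1] + fit$lambda_main * drop(K21 %*% adj)
    return(tibble::tibble(hybrid_id = rep(as.character(ids), 1),
                          environment = fit$envs[1], y_hat = y_hat))
  }
  st <- gxe_stack(fit$Y, fit$K)
  V011 <- st$KJ * fit$lambda_main + st$KI * fit$lambda_gxe +
    diag(length(st$y))
  resid <- st$y - drop(st$X %*% fit$beta_hat)
  adj <- solve(V011, resid)                       # length n1 * E
  out <- vector("list", E)
  for (e in seq_len(E)) {
    # n2 x (n1 E) covariance row-block for environment e
    C_e <- do.call(cbind, lapply(seq_len(E), function(f) {
      K21 * (fit$lambda_main + if (e == f) fit$lambda_gxe else 0)
    }))
    out[[e]] <- tibble::tibble(hybrid_id = as.character(ids),
                               environment = fit$envs[e],
                               y_hat = fit$beta_hat[e] + drop(C_e %*% adj))
  }
  dplyr::bind_rows(out)
}
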