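#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit
#'
#' One row per estimated parameter: fixed effects, the variance ratio and
#' the two variance components.
#'
#' @param x A `reml_fit` from [fit_reml()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("beta", seq_along(x$beta_hat)),
             "lambda", "sigma2", "phi2"),
    estimate = c(x$beta_hat, x$lambda_hat, x$sigma2_hat, x$phi2_hat))
}

#' Glance at a REML fit
#'
#' @param x A `reml_fit` from [fit_reml()].
#' @param ... Unused.
#' @return A one-row tibble: `lambda`, `sigma2`, `phi2`, `h2_genomic`,
#'   `restricted_loglik`, `n`, `n_iter`, `converged`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda_hat, sigma2 = x$sigma2_hat,
                 phi2 = x$phi2_hat, h2_genomic = x$h2_genomic,
                 restricted_loglik = x$restricted_loglik,
                 n = x$n, n_iter = x$n_iter, converged = x$converged)
}

#' @rdname tidy.reml_fit
#' @export
tidy.reml_fit_ad <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("beta", seq_along(x$beta_hat)),
             "lambda_a", "lambda_d", "sigma2", "phi2_a", "phi2_d"),
    estimate = c(x$beta_hat, x$lambda_a, x$lambda_d, x$sigma2_hat,
                 x$phi2_a, x$phi2_d))
}

#' @rdname glance.reml_fit
#' @export
glance.reml_fit_ad <- function(x, ...) {
  tibble::tibble(lambda_a = x$lambda_a, lambda_d = x$lambda_d,
                 sigma2 = x$sigma2_hat, phi2_a = x$phi2_a,
                 phi2_d = x$phi2_d,
                 restricted_loglik = x$restricted_loglik,
                 n = x$n, converged = x$converged)
}

#' @rdname tidy.reml_fit
#' @export
tidy.reml_fit_gxe <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("mean_", x$envs), "lambda_main", "lambda_gxe", "sigma2"),
    estimate = c(unname(x$beta_hat), x$lambda_main, x$lambda_gxe,
                 x$sigma2_hat))
}

#' @rdname glance.reml_fit
#' @export
glance.reml_fit_gxe <- function(x, ...) {
  tibble::tibble(lambda_main = x$lambda_main, lambda_gxe = x$lambda_gxe,
                 sigma2 = x$sigma2_hat, phi2_main = x$phi2_main,
                 phi2_gxe = x$phi2_gxe,
                 restricted_loglik = x$restricted_loglik,
                 n_env = length(x$envs), converged = x$converged)
}

#' Tidy cross-validation abilities
#'
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return The per-replicate ability tibble (`trait`, `replicate`,
#'   `ability`).
#' @export
tidy.cv_result <- function(x, ...) x$ability

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::mutate(x$summary, k = x$k, replicates = x$replicates)
}

#' Tidy CRBD variance components
#'
#' @param x A `variance_components` from [fit_crbd()].
#' @param ... Unused.
#' @return The ANOVA-style table with the variance-component estimates
#'   appended.
#' @export
tidy.variance_components <- function(x, ...) {
  dplyr::mutate(x$table,
                estimate = c(x$sigma2_G_raw, NA_real_, x$sigma2_E))
}

#' @rdname tidy.variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(sigma2_G = x$sigma2_G, sigma2_G_raw = x$sigma2_G_raw,
                 sigma2_E = x$sigma2_E, h2_broad = x$h2_broad,
                 n_hybrids = x$n_hybrids, n_blocks = x$n_blocks,
                 method = x$method)
}
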