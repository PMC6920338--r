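#' Marker-inferred additive kinship matrix
#'
#' Computes the relationship matrix K = (1/m) * sum_k Z_k Z_k^T, where Z_k is
#' the vector of numeric genotype codes at marker k across individuals. By
#' default the codes enter as given, with no centering and no
#' allele-frequency scaling, so K is the raw cross-product of the code matrix
#' divided by the number of markers. A centered VanRaden-style variant
#' (codes centered by twice the allele frequency and scaled by
#' `2 * sum(p_k (1 - p_k))`) is available via `method = "vanraden"`.
#'
#' @param G A [genotype_matrix()] with no missing entries (impute first, see
#'   [impute_mean()]).
#' @param method `"identity"` (default; codes as given) or `"vanraden"`
#'   (frequency-centered).
#'
#' @return An n x n symmetric positive semi-definite matrix of class
#'   `kinship_matrix`, individuals in rows and columns, with attribute
#'   `n_markers`.
#' @export
compute_kinship <- function(G, method = c("identity", "vanraden")) {
  method <- match.arg(method)
  G <- as_genotype_matrix(G)
  if (nrow(G) == 0) stop("no markers; cannot compute kinship.", call. = FALSE)
  if (anyNA(G)) {
    stop("genotype matrix contains missing values; impute first.",
         call. = FALSE)
  }
  Z <- unclass(G)
  if (method == "identity") {
    K <- crossprod(Z) / nrow(Z)
  } else {
    p <- (rowMeans(Z) + 1) / 2
    Zc <- Z - (2 * p - 1)
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0) stop("all markers monomorphic; VanRaden scaling undefined.",
                         call. = FALSE)
    K <- crossprod(Zc) / denom
  }
  new_kinship(K, colnames(G), nrow(G))
}

#' Dominance kinship matrix from heterozygosity codes
#'
#' Recodes each genotype to its (expected) heterozygosity
#' `W = max(0, 1 - |2 Z|)`: heterozygote (0) -> 1, homozygotes (+-1) -> 0, and
#' the half codes +-0.5 from a residually heterozygous parent -> 0.5, the
#' probability that the hybrid is heterozygous at the locus. The dominance
#' relationship matrix is then K_D = (1/m) * sum_k W_k W_k^T, mirroring the
#' additive construction on the dominance design.
#'
#' @inheritParams compute_kinship
#' @return An n x n `kinship_matrix` (see [compute_kinship()]).
#' @export
compute_dominance_kinship <- function(G) {
  G <- as_genotype_matrix(G)
  if (nrow(G) == 0) stop("no markers; cannot compute kinship.", call. = FALSE)
  if (anyNA(G)) {
    stop("genotype matrix contains missing values; impute first.",
         call. = FALSE)
  }
  W <- 1 - abs(2 * unclass(G))
  W[W < 0] <- 0
  new_kinship(crossprod(W) / nrow(W), colnames(G), nrow(G))
}

new_kinship <- function(K, ids, n_markers) {
  K <- (K + t(K)) / 2
  dimnames(K) <- list(ids, ids)
  attr(K, "n_markers") <- n_markers
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d individuals (from %s markers)\n",
              nrow(x), attr(x, "n_markers") %||% "?"))
  cat(sprintf("  mean diagonal: %.4f\n", mean(diag(x))))
  invisible(x)
}

as_kinship <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kinship matrix must be square.", call. = FALSE)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("kinship matrix must be symmetric.", call. = FALSE)
  }
  K
}
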