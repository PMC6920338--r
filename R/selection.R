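#' Default economic weights for the ten-trait rice breeding index
#'
#' Weights (proportions summing to one) for yield (YD), panicle number (PN),
#' grain number per panicle (GN), seed setting rate (SSR), thousand-grain
#' weight (KGW), heading date (HD), plant height (PH), panicle length (PL),
#' grain width (GW) and grain length (GL): yield alone carries 40%, the four
#' yield components 35% combined, and the remaining traits 5% each.
#' @format Named numeric vector of length 10 summing to 1.
#' @export
rice_index_weights <- c(YD = 0.4, PN = 0.1, GN = 0.1, SSR = 0.1,
                        KGW = 0.05, HD = 0.05, PH = 0.05, PL = 0.05,
                        GW = 0.05, GL = 0.05)

#' Standardize predicted trait values
#'
#' Column-wise z-scores of a hybrid x trait matrix of predicted values. The
#' reference population is the candidate set being ranked, and the default
#' scale is the population standard deviation (divisor n); set
#' `population_sd = FALSE` for the sample convention (divisor n - 1).
#'
#' @param predicted Numeric matrix or data frame, hybrids in rows, traits in
#'   columns (a `hybrid_id` column, if present, is carried through).
#' @param population_sd Use divisor n (default `TRUE`).
#' @return A tibble with `hybrid_id` and one standardized column per trait.
#' @export
standardize_traits <- function(predicted, population_sd = TRUE) {
  prep <- split_pred(predicted)
  M <- prep$M
  if (nrow(M) < 2) stop("need at least two hybrids.", call. = FALSE)
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  if (population_sd) sdv <- sdv * sqrt((nrow(M) - 1) / nrow(M))
  zero <- sdv == 0 | is.na(sdv)
  if (any(zero)) {
    stop(sprintf("zero-variance trait(s): %s",
                 paste(colnames(M)[zero], collapse = ", ")), call. = FALSE)
  }
  Z <- sweep(sweep(M, 2, mu), 2, sdv, "/")
  dplyr::bind_cols(tibble::tibble(hybrid_id = prep$ids),
                   tibble::as_tibble(Z))
}

split_pred <- function(predicted) {
  predicted <- as.data.frame(predicted)
  if ("hybrid_id" %in% names(predicted)) {
    ids <- as.character(predicted$hybrid_id)
    M <- as.matrix(predicted[setdiff(names(predicted), "hybrid_id")])
  } else {
    ids <- rownames(predicted) %||% paste0("hyb", seq_len(nrow(predicted)))
    M <- as.matrix(predicted)
  }
  storage.mode(M) <- "double"
  list(ids = ids, M = M)
}

#' Weighted breeding index
#'
#' The breeding index of hybrid j is I_j = sum_k w_k z_jk, the weighted sum
#' of its standardized predicted trait values. With the default weights a
#' standardized yield of 2 contributes 0.4 x 2 = 0.8 to the index.
#'
#' @param predicted Hybrid x trait matrix or data frame of predicted values
#'   (standardized internally unless `standardized = TRUE`).
#' @param weights Named numeric vector of non-negative weights summing to 1
#'   (default [rice_index_weights] restricted to the supplied traits is NOT
#'   assumed: names must match the trait columns exactly).
#' @param standardized Set `TRUE` when `predicted` is already column
#'   standardized.
#' @param population_sd Passed to [standardize_traits()].
#' @param direction Optional named vector of +1/-1 per trait flipping the
#'   sign of a standardized trait before weighting (all traits default to
#'   "larger is better"; e.g. set -1 for heading date when earliness is
#'   preferred). Traits not named keep +1.
#' @return An object of class `breeding_index`: a tibble with `hybrid_id`,
#'   `index` and `rank` (1 = best), with the standardized trait matrix in
#'   attribute `"standardized"`.
#' @export
breeding_index <- function(predicted, weights = rice_index_weights,
                           standardized = FALSE, population_sd = TRUE,
                           direction = NULL) {
  if (any(weights < 0)) stop("weights must be non-negative.", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1.", call. = FALSE)
  }
  std <- if (standardized) {
    prep <- split_pred(predicted)
    dplyr::bind_cols(tibble::tibble(hybrid_id = prep$ids),
                     tibble::as_tibble(prep$M))
  } else {
    standardize_traits(predicted, population_sd = population_sd)
  }
  traits <- setdiff(names(std), "hybrid_id")
  if (is.null(names(weights)) && length(weights) == length(traits)) {
    names(weights) <- traits
  }
  if (!setequal(names(weights), traits)) {
    stop("weight names do not match the trait columns.", call. = FALSE)
  }
  Z <- as.matrix(std[traits])
  if (!is.null(direction)) {
    if (is.null(names(direction)) || !all(names(direction) %in% traits) ||
        !all(direction %in% c(-1, 1))) {
      stop("`direction` must be a named vector of +1/-1 over trait names.",
           call. = FALSE)
    }
    sgn <- stats::setNames(rep(1, length(traits)), traits)
    sgn[names(direction)] <- direction
    Z <- sweep(Z, 2, sgn[traits], "*")
  }
  idx <- drop(Z %*% weights[traits])
  out <- tibble::tibble(hybrid_id = std$hybrid_id, index = idx)
  out$rank <- rank(-out$index, ties.method = "first")
  attr(out, "standardized") <- std
  attr(out, "weights") <- weights[traits]
  class(out) <- c("breeding_index", class(out))
  out
}

#' Select the extreme hybrids by breeding index
#'
#' Returns the ids of the `n_top` largest and `n_bottom` smallest index
#' scores. Ties are broken by hybrid id in lexicographic order so the
#' selection is deterministic; the two sets never overlap.
#'
#' @param result A `breeding_index` tibble, or any data frame with
#'   `hybrid_id` and `index` columns.
#' @param n_top,n_bottom Sizes of the two tails (default 200 each).
#' @return List with character vectors `top` and `bottom`.
#' @export
select_extremes <- function(result, n_top = 200, n_bottom = 200) {
  result <- as.data.frame(result)
  stopifnot(all(c("hybrid_id", "index") %in% names(result)))
  n <- nrow(result)
  if (n_top + n_bottom > n) {
    stop("n_top + n_bottom exceeds the number of hybrids.", call. = FALSE)
  }
  ord_desc <- order(-result$index, result$hybrid_id)
  top <- result$hybrid_id[ord_desc][seq_len(n_top)]
  # bottom tail drawn from the remaining hybrids so ties spanning both
  # tails cannot make the sets overlap
  rest <- result[!result$hybrid_id %in% top, ]
  ord_asc <- order(rest$index, rest$hybrid_id)
  bottom <- rest$hybrid_id[ord_asc][seq_len(n_bottom)]
  list(top = top, bottom = bottom)
}

#' Principal component summary of predicted trait values
#'
#' PCA of the column-standardized hybrid x trait matrix: eigenvalues of the
#' trait correlation structure (non-increasing, summing to the number of
#' traits) and the component scores used to visualise the spread of a
#' candidate population.
#'
#' @param predicted Hybrid x trait matrix or data frame of predicted values.
#' @param n_components Number of components to return (default: all traits).
#' @param population_sd Passed to [standardize_traits()].
#' @return An object of class `pca_summary`: list with `eigenvalues`
#'   (length = number of traits), `scores` (tibble: hybrid_id, PC1..), and
#'   `loadings`.
#' @export
pca_summary <- function(predicted, n_components = NULL,
                        population_sd = TRUE) {
  std <- standardize_traits(predicted, population_sd = population_sd)
  traits <- setdiff(names(std), "hybrid_id")
  if (is.null(n_components)) n_components <- length(traits)
  if (n_components > length(traits)) {
    stop("`n_components` exceeds the number of traits.", call. = FALSE)
  }
  Z <- as.matrix(std[traits])
  n <- nrow(Z)
  # covariance of standardized columns with the same divisor convention
  Cv <- crossprod(Z) / if (population_sd) n else n - 1
  e <- eigen(Cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  scores <- Z %*% e$vectors[, keep, drop = FALSE]
  colnames(scores) <- paste0("PC", keep)
  structure(list(
    eigenvalues = e$values,
    scores = dplyr::bind_cols(tibble::tibble(hybrid_id = std$hybrid_id),
                              tibble::as_tibble(scores)),
    loadings = stats::setNames(as.data.frame(e$vectors[, keep, drop = FALSE]),
                               paste0("PC", keep))
  ), class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("<pca_summary>\n  eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}
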