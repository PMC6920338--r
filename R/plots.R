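#' Plot per-replicate cross-validation abilities
#'
#' Boxplot of prediction ability across replicates, one box per trait, with
#' the replicate values overlaid.
#'
#' @param object A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$ability,
                  ggplot2::aes(x = .data$trait, y = .data$ability)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "prediction ability (r)",
                  title = sprintf("%d-fold cross-validation, %d replicates",
                                  object$k, object$replicates)) +
    ggplot2::theme_minimal()
}

#' Scree plot of a predicted-trait PCA
#'
#' Eigenvalue against component number for the column-standardized
#' hybrid x trait matrix.
#'
#' @param object A `pca_summary` from [pca_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_summary <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "principal component", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' Distribution of breeding-index scores with selected tails
#'
#' Histogram of the index with the top/bottom selections shaded, mirroring
#' how extreme candidates are picked for field evaluation.
#'
#' @param object A `breeding_index` from [breeding_index()].
#' @param n_top,n_bottom Tail sizes to highlight (defaults 200, capped at
#'   what the candidate set allows).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breeding_index <- function(object, n_top = 200, n_bottom = 200, ...) {
  n <- nrow(object)
  n_top <- min(n_top, floor(n / 2))
  n_bottom <- min(n_bottom, n - n_top)
  sel <- select_extremes(object, n_top = n_top, n_bottom = n_bottom)
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    tail = dplyr::case_when(.data$hybrid_id %in% sel$top ~ "top",
                            .data$hybrid_id %in% sel$bottom ~ "bottom",
                            TRUE ~ "unselected"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, fill = .data$tail)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::scale_fill_manual(values = c(top = "#2166ac",
                                          bottom = "#ffcc33",
                                          unselected = "grey80")) +
    ggplot2::labs(x = "breeding index", y = "hybrids") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
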