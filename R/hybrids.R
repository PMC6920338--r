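#' Deduce the genotype code of a hybrid from its two parents
#'
#' For fully inbred parents the F1 genotype at a biallelic locus is determined:
#' the hybrid code is the mean of the two parental codes. A1A1 (-1) crossed
#' with A2A2 (1) gives the heterozygote 0; a residually heterozygous parent
#' (code 0) produces the half codes, e.g. A1A1 x A1A2 gives (-1 + 0)/2 = -0.5.
#' Missing data in either parent propagates to the hybrid.
#'
#' @param parent1_code,parent2_code Numeric vectors of parental genotype codes,
#'   each in \{-1, 0, 1\} or `NA` (parents are inbred; 0 marks residual
#'   heterozygosity). Recycled to a common length.
#'
#' @return Numeric vector of hybrid codes in \{-1, -0.5, 0, 0.5, 1\} or `NA`.
#' @export
#' @examples
#' deduce_hybrid_code(-1, 0)  # -0.5
#' deduce_hybrid_code(1, 0)   # 0.5
#' deduce_hybrid_code(c(-1, 1), c(-1, -1))
deduce_hybrid_code <- function(parent1_code, parent2_code) {
  check_codes(parent1_code, allowed = c(-1, 0, 1))
  check_codes(parent2_code, allowed = c(-1, 0, 1))
  (parent1_code + parent2_code) / 2
}

#' Canonical hybrid identifier for a cross
#'
#' Parent ids are sorted so that the reciprocal crosses (P1, P2) and (P2, P1)
#' map to the same identifier.
#'
#' @param parent1,parent2 Character vectors of parent ids.
#' @return Character vector `"A_x_B"` with `A <= B` lexicographically.
#' @export
hybrid_id <- function(parent1, parent2) {
  paste(pmin(parent1, parent2), pmax(parent1, parent2), sep = "_x_")
}

#' Deduce genotypes for a set of crosses
#'
#' Builds the in-silico genotype matrix of hybrids from the genotypes of their
#' inbred parents, marker by marker, via [deduce_hybrid_code()]. Duplicate
#' crosses (including reciprocals) are collapsed with a warning.
#'
#' @param parents A [genotype_matrix()] of the parental lines (codes in
#'   \{-1, 0, 1\} or `NA`).
#' @param crosses A data frame with two character columns naming the parents of
#'   each cross (any column names; the first two columns are used), or a
#'   two-column character matrix.
#'
#' @return A [genotype_matrix()] with one column per unique cross, column ids
#'   formed by [hybrid_id()], markers as in `parents`.
#' @export
build_hybrid_matrix <- function(parents, crosses) {
  parents <- as_genotype_matrix(parents)
  crosses <- as.data.frame(crosses)
  if (ncol(crosses) < 2) {
    stop("`crosses` needs at least two columns (the two parent ids).",
         call. = FALSE)
  }
  p1 <- as.character(crosses[[1]])
  p2 <- as.character(crosses[[2]])
  unknown <- setdiff(unique(c(p1, p2)), colnames(parents))
  if (length(unknown)) {
    stop(sprintf("unknown parent id(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  ids <- hybrid_id(p1, p2)
  if (anyDuplicated(ids)) {
    warning(sprintf("%d duplicate cross(es) removed.", sum(duplicated(ids))),
            call. = FALSE)
    keep <- !duplicated(ids)
    p1 <- p1[keep]; p2 <- p2[keep]; ids <- ids[keep]
  }
  codes <- (parents[, p1, drop = FALSE] + parents[, p2, drop = FALSE]) / 2
  genotype_matrix(codes, marker_ids = rownames(parents), individual_ids = ids,
                  chrom = attr(parents, "chrom"), pos = attr(parents, "pos"))
}
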