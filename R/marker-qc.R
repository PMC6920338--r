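#' Filter markers on minor allele frequency and missingness
#'
#' Retains markers whose minor allele frequency is strictly above `maf_min`
#' and whose fraction of missing calls is at most `missing_max`. The allele
#' frequency is computed from the numeric codes as `p = (mean(code) + 1) / 2`
#' over non-missing entries (half codes contribute their expected allele
#' dosage), and MAF is `min(p, 1 - p)`. Missingness is tested first; the MAF
#' of a marker failing the missingness filter is not counted against the MAF
#' criterion in the report.
#'
#' @param G A [genotype_matrix()].
#' @param maf_min Minor-allele-frequency threshold; markers with MAF strictly
#'   greater are kept. Must be in `[0, 0.5)`. Default 0.1.
#' @param missing_max Maximum tolerated fraction of missing calls per marker,
#'   in `[0, 1]`. Default 0.25.
#'
#' @return The filtered [genotype_matrix()], with a tibble attribute
#'   `"filter_report"` (see [filter_report()]) counting markers removed per
#'   criterion.
#' @export
filter_markers <- function(G, maf_min = 0.1, missing_max = 0.25) {
  G <- as_genotype_matrix(G)
  if (nrow(G) == 0 || ncol(G) == 0) {
    stop("empty genotype matrix.", call. = FALSE)
  }
  stopifnot(maf_min >= 0, maf_min < 0.5, missing_max >= 0, missing_max <= 1)
  miss_frac <- rowMeans(is.na(G))
  p <- (rowMeans(G, na.rm = TRUE) + 1) / 2
  maf <- pmin(p, 1 - p)
  ok_miss <- miss_frac <= missing_max
  ok_maf <- !is.nan(maf) & maf > maf_min
  keep <- ok_miss & ok_maf
  report <- tibble::tibble(
    criterion = c("input", "missingness", "maf", "kept"),
    n_markers = c(nrow(G), sum(!ok_miss), sum(ok_miss & !ok_maf), sum(keep))
  )
  if (!any(keep)) {
    stop("all markers removed by filtering; no marker panel left.",
         call. = FALSE)
  }
  out <- subset_markers(G, keep)
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_markers
#' @export
filter_report <- function(G) {
  attr(G, "filter_report")
}

subset_markers <- function(G, keep) {
  genotype_matrix(unclass(G)[keep, , drop = FALSE],
                  marker_ids = rownames(G)[keep],
                  individual_ids = colnames(G),
                  chrom = attr(G, "chrom")[keep],
                  pos = attr(G, "pos")[keep])
}

#' Impute missing genotype codes with the marker mean
#'
#' Replaces each missing call by the mean non-missing code of its marker.
#' This preserves the marker's allele frequency and is the package default
#' after filtering; markers that are entirely missing cannot be imputed and
#' raise an error (they should have been removed by [filter_markers()]).
#'
#' @param G A [genotype_matrix()].
#' @return A [genotype_matrix()] with no missing entries. Imputed values are
#'   generally not members of the discrete code set; downstream kinship
#'   computations accept them.
#' @export
impute_mean <- function(G) {
  G <- as_genotype_matrix(G)
  if (!anyNA(G)) return(G)
  all_missing <- rowSums(!is.na(G)) == 0
  if (any(all_missing)) {
    stop(sprintf("%d marker(s) entirely missing; filter before imputing.",
                 sum(all_missing)), call. = FALSE)
  }
  m <- rowMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  out <- unclass(G)
  out[idx] <- m[idx[, 1]]
  out <- genotype_matrix_skip_check(out, G)
  out
}

# rebuild a genotype_matrix whose entries may now be off-grid (imputed means)
genotype_matrix_skip_check <- function(codes, template) {
  dimnames(codes) <- dimnames(template)
  attr(codes, "chrom") <- attr(template, "chrom")
  attr(codes, "pos") <- attr(template, "pos")
  class(codes) <- c("genotype_matrix", "matrix", "array")
  codes
}
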