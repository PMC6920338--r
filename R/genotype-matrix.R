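#' Construct a genotype matrix
#'
#' A `genotype_matrix` stores numeric SNP genotype codes for a panel of
#' individuals, markers in rows and individuals in columns. Codes follow the
#' homozygote/heterozygote convention used throughout the package: -1 for one
#' homozygote, 0 for the heterozygote, 1 for the other homozygote. Hybrids
#' deduced from parents with residual heterozygosity can additionally carry
#' the half codes -0.5 and 0.5 (the mean of the two parental codes), so the
#' full set of legal non-missing values is \{-1, -0.5, 0, 0.5, 1\}.
#'
#' @param codes Numeric matrix, markers x individuals. Entries must be in
#'   \{-1, -0.5, 0, 0.5, 1\} or `NA`.
#' @param marker_ids Character vector of unique marker identifiers. Defaults
#'   to existing rownames or `mk1..mkm`.
#' @param individual_ids Character vector of unique individual identifiers.
#'   Defaults to existing colnames or `id1..idn`.
#' @param chrom,pos Optional chromosome labels and 1-based positions, one per
#'   marker. Never required for any computation.
#'
#' @return A numeric matrix of class `genotype_matrix` with marker ids as
#'   rownames and individual ids as colnames; `chrom`/`pos`, when given, are
#'   kept as attributes.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(-1, 1, 0, 1), 2, 2),
#'                      marker_ids = c("m1", "m2"),
#'                      individual_ids = c("P1", "P2"))
genotype_matrix <- function(codes, marker_ids = NULL, individual_ids = NULL,
                            chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(marker_ids)) {
    marker_ids <- rownames(codes) %||% paste0("mk", seq_len(nrow(codes)))
  }
  if (is.null(individual_ids)) {
    individual_ids <- colnames(codes) %||% paste0("id", seq_len(ncol(codes)))
  }
  if (length(marker_ids) != nrow(codes)) {
    stop("`marker_ids` must have one entry per row of `codes`.", call. = FALSE)
  }
  if (length(individual_ids) != ncol(codes)) {
    stop("`individual_ids` must have one entry per column of `codes`.",
         call. = FALSE)
  }
  if (anyDuplicated(marker_ids)) {
    stop("marker ids must be unique.", call. = FALSE)
  }
  if (anyDuplicated(individual_ids)) {
    stop("individual ids must be unique.", call. = FALSE)
  }
  check_codes(codes)
  dimnames(codes) <- list(as.character(marker_ids), as.character(individual_ids))
  if (!is.null(chrom)) {
    stopifnot(length(chrom) == nrow(codes))
    attr(codes, "chrom") <- as.character(chrom)
  }
  if (!is.null(pos)) {
    stopifnot(length(pos) == nrow(codes), all(is.na(pos) | pos >= 1))
    attr(codes, "pos") <- as.numeric(pos)
  }
  class(codes) <- c("genotype_matrix", class(codes))
  codes
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d markers x %d individuals\n",
              nrow(x), ncol(x)))
  miss <- mean(is.na(x))
  cat(sprintf("  missing: %.2f%%  codes: {%s}\n", 100 * miss,
              paste(sort(unique(x[!is.na(x)])), collapse = ", ")))
  invisible(x)
}

# legal numeric genotype codes (parental plus deduced hybrid half-codes)
genotype_codes <- c(-1, -0.5, 0, 0.5, 1)

check_codes <- function(codes, allowed = genotype_codes) {
  vals <- codes[!is.na(codes)]
  bad <- vals[is.na(match_num(vals, allowed))]
  if (length(bad)) {
    stop(sprintf("invalid genotype code(s): %s (allowed: %s)",
                 paste(utils::head(unique(bad), 5), collapse = ", "),
                 paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# match numeric values against a small allowed set with tolerance
match_num <- function(x, table, tol = 1e-9) {
  idx <- rep(NA_integer_, length(x))
  for (i in seq_along(table)) {
    idx[abs(x - table[i]) < tol] <- i
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x)
  genotype_matrix(x)
}
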