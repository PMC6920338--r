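#' Read a genotype matrix from VCF or the tabular dialect
#'
#' VCF input keeps biallelic SNP records only (multi-allelic or non-SNP
#' records are skipped, with counts reported in a message) and maps the GT
#' field as REF/REF -> -1, heterozygote -> 0, ALT/ALT -> 1, missing -> `NA`.
#' The tabular dialect is a comma- or tab-separated text file, first column
#' the marker id, header row of individual ids, cells in
#' \{-1, -0.5, 0, 0.5, 1, NA\}.
#'
#' @param path File path.
#' @param format `"auto"` (by extension, default), `"vcf"` or `"table"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("genotype file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "table"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_table(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # 1-row safety
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message(sprintf("skipped %d non-biallelic-SNP record(s).", n_skipped))
  }
  if (!any(snp)) stop("no biallelic SNP records in VCF.", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  alleles <- gsub("[|]", "/", gt)
  code <- matrix(NA_real_, nrow(alleles), ncol(alleles),
                 dimnames = dimnames(alleles))
  code[alleles %in% c("0/0")] <- -1
  code[alleles %in% c("0/1", "1/0")] <- 0
  code[alleles %in% c("1/1")] <- 1
  ids <- fix[snp, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste(fix[snp, "CHROM"][blank], fix[snp, "POS"][blank],
                      sep = "_")
  genotype_matrix(code, marker_ids = ids,
                  individual_ids = colnames(gt),
                  chrom = fix[snp, "CHROM"],
                  pos = as.numeric(fix[snp, "POS"]))
}

read_genotypes_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("tabular genotype file needs a marker-id column plus individuals.",
         call. = FALSE)
  }
  M <- as.matrix(df[-1])
  storage.mode(M) <- "double"
  genotype_matrix(M, marker_ids = as.character(df[[1]]),
                  individual_ids = colnames(df)[-1])
}

#' Write a genotype matrix in the tabular dialect
#'
#' Comma-separated UTF-8 text, `marker_id` first column, one column per
#' individual, `NA` for missing, full double precision so that read/write
#' round-trips are lossless.
#'
#' @param G A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  G <- as_genotype_matrix(G)
  df <- data.frame(marker_id = rownames(G),
                   format(unclass(G), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("marker_id", colnames(G))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write kinship matrices as labelled square tables
#'
#' @param K A `kinship_matrix` (or plain symmetric matrix).
#' @param path File path.
#' @return `write_kinship` returns `path` invisibly; `read_kinship` returns a
#'   `kinship_matrix`.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = rownames(K) %||% paste0("id", seq_len(nrow(K))),
                   format(unclass(K), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(K) %||% df$id)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[-1])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(df[[1]])
  new_kinship(M, rownames(M), NA_integer_)
}

#' Read index weights from YAML or CSV
#'
#' YAML files map trait names to weights; CSV files have columns
#' `trait, weight`.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.csv`.
#' @return Named numeric vector of weights.
#' @export
read_weights <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    w <- unlist(yaml::read_yaml(path))
    return(stats::setNames(as.numeric(w), names(w)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$weight), df$trait)
}

#' Run the full prediction pipeline on synthetic or on-disk data
#'
#' Chains the package stages — marker filtering, mean imputation, hybrid
#' deduction, kinship, REML fit, BLUP prediction of the test set, optional
#' cross-validation, and breeding-index ranking across traits — writing every
#' intermediate artifact as CSV into `out_dir` and logging one line per
#' stage to `stderr`. Deterministic for a given `seed`.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `genotypes` (path, optional when `simulate` is given), `pheno` (path,
#'   long CSV hybrid_id/environment/value or wide hybrid_id + traits),
#'   `crosses` (path, optional CSV with two parent columns), `simulate`
#'   (list of [sim_config()] arguments, alternative to files),
#'   `maf_min`, `missing_max`, `cv` (logical), `k`, `replicates`,
#'   `n_top`/`n_bottom`, `seed`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the created artifacts (paths) and key
#'   objects (`fit`, `predictions`, `cv`, `index` where applicable).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[hybridgs] ", fmt), ...))
  }
  artifacts <- list()

  if (!is.null(config$simulate)) {
    log_stage("simulate: generating synthetic panel")
    cfg <- do.call(sim_config, utils::modifyList(config$simulate,
                                                 list(seed = seed)))
    bundle <- make_training_and_test(
      cfg,
      n_train = config$n_train %||% 200,
      n_test = config$n_test %||% 50)
    parents <- bundle$parents
    pheno_long <- bundle$pheno_train
    hybrids <- bundle$hybrids
    train_ids <- bundle$train_ids
    test_ids <- bundle$test_ids
  } else {
    if (is.null(config$genotypes) || !file.exists(config$genotypes)) {
      stop(sprintf("genotype file not found: %s",
                   config$genotypes %||% "<missing>"), call. = FALSE)
    }
    if (is.null(config$pheno) || !file.exists(config$pheno)) {
      stop(sprintf("phenotype file not found: %s",
                   config$pheno %||% "<missing>"), call. = FALSE)
    }
    log_stage("read: %s", config$genotypes)
    parents <- read_genotypes(config$genotypes)
    pheno_long <- utils::read.csv(config$pheno, stringsAsFactors = FALSE)
    if (!"environment" %in% names(pheno_long)) {
      pheno_long <- tidyr::pivot_longer(pheno_long, -"hybrid_id",
                                        names_to = "trait",
                                        values_to = "value")
      pheno_long$environment <- "env1"
    }
    if (!"value" %in% names(pheno_long)) {
      stop("phenotype CSV needs a `value` column (long format).",
           call. = FALSE)
    }
    crosses <- utils::read.csv(config$crosses, stringsAsFactors = FALSE)
    log_stage("filter: maf > %s, missing <= %s",
              config$maf_min %||% 0.1, config$missing_max %||% 0.25)
    parents <- filter_markers(parents,
                              maf_min = config$maf_min %||% 0.1,
                              missing_max = config$missing_max %||% 0.25)
    hybrids <- impute_mean(build_hybrid_matrix(parents, crosses[1:2]))
    train_ids <- intersect(colnames(hybrids), unique(pheno_long$hybrid_id))
    test_ids <- setdiff(colnames(hybrids), train_ids)
  }

  artifacts$genotypes <- file.path(out_dir, "hybrid_genotypes.csv")
  write_genotypes(hybrids, artifacts$genotypes)
  log_stage("kinship: %d hybrids, %d markers",
            ncol(hybrids), nrow(hybrids))
  K <- compute_kinship(hybrids)
  artifacts$kinship <- file.path(out_dir, "kinship.csv")
  write_kinship(K, artifacts$kinship)

  # per-environment means as the working phenotype
  ph <- dplyr::summarise(
    dplyr::group_by(pheno_long, .data$hybrid_id),
    value = mean(.data$value), .groups = "drop")
  ph <- ph[match(intersect(train_ids, ph$hybrid_id), ph$hybrid_id), ]
  y <- ph$value
  log_stage("fit: REML on %d training hybrids", length(y))
  fit <- fit_reml(y, K[ph$hybrid_id, ph$hybrid_id])
  fit_tbl <- glance(fit)
  artifacts$fit <- file.path(out_dir, "fit.csv")
  utils::write.csv(fit_tbl, artifacts$fit, row.names = FALSE)

  preds <- NULL
  if (length(test_ids)) {
    log_stage("predict: %d test hybrids", length(test_ids))
    preds <- blup_predict(fit, K[test_ids, ph$hybrid_id, drop = FALSE])
    artifacts$predictions <- file.path(out_dir, "predictions.csv")
    utils::write.csv(preds, artifacts$predictions, row.names = FALSE)
  }

  cv <- NULL
  if (isTRUE(config$cv)) {
    log_stage("cv: %d-fold x %d replicates", config$k %||% 10,
              config$replicates %||% 10)
    cv <- cross_validate(K[ph$hybrid_id, ph$hybrid_id],
                         data.frame(hybrid_id = ph$hybrid_id, trait = y),
                         k = config$k %||% 10,
                         replicates = config$replicates %||% 10,
                         seed = seed)
    artifacts$cv <- file.path(out_dir, "cv_ability.csv")
    utils::write.csv(cv$ability, artifacts$cv, row.names = FALSE)
  }

  index <- NULL
  if (!is.null(preds) && nrow(preds) >= 3) {
    # single-trait ranking: the index degenerates to the standardized trait
    log_stage("index: ranking %d candidates", nrow(preds))
    pred_mat <- data.frame(hybrid_id = preds$hybrid_id, trait = preds$y_hat)
    index <- breeding_index(pred_mat, weights = c(trait = 1))
    n_top <- min(config$n_top %||% 200, floor(nrow(index) / 2))
    n_bot <- min(config$n_bottom %||% 200, ceiling(nrow(index) / 2) - 1)
    sel <- select_extremes(index, n_top = n_top, n_bottom = n_bot)
    out <- dplyr::mutate(index,
                         selected_top = .data$hybrid_id %in% sel$top,
                         selected_bottom = .data$hybrid_id %in% sel$bottom)
    artifacts$index <- file.path(out_dir, "index.csv")
    utils::write.csv(out, artifacts$index, row.names = FALSE)
  }
  log_stage("done: %d artifact(s) in %s", length(artifacts), out_dir)
  invisible(list(artifacts = artifacts, fit = fit, predictions = preds,
                 cv = cv, index = index))
}
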