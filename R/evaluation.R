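#' Random K-fold partition
#'
#' Splits `n` individuals into `k` folds of near-equal size (sizes differ by
#' at most one) via a seeded random permutation. The global RNG state is left
#' untouched.
#'
#' @param n Number of individuals.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed making the partition reproducible.
#' @return Integer vector of fold labels in `1..k`, length `n`.
#' @export
kfold_partition <- function(n, k, seed) {
  if (k < 2 || k > n) stop("need 2 <= k <= n folds.", call. = FALSE)
  withr::with_seed(seed, {
    perm <- sample.int(n)
  })
  labels <- integer(n)
  # fold sizes: ceiling(n/k) for the first n %% k folds, floor otherwise
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels[perm] <- rep(seq_len(k), times = sizes)
  labels
}

#' Prediction ability
#'
#' The Pearson correlation between observed and predicted trait values; the
#' standard summary of genomic prediction accuracy in cross-validation.
#'
#' @param y_obs,y_pred Numeric vectors of equal length (>= 3).
#' @return Scalar correlation in `[-1, 1]`.
#' @export
prediction_ability <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 3) {
    stop("observed and predicted vectors must have equal length >= 3.",
         call. = FALSE)
  }
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0) {
    stop("prediction ability undefined: zero variance.", call. = FALSE)
  }
  stats::cor(y_obs, y_pred)
}

#' Replicated K-fold cross-validation of GBLUP prediction
#'
#' For each replicate the sample is partitioned into `k` folds with a fresh
#' seed (`seed + replicate - 1`); each fold is predicted from a REML fit on
#' the remaining folds via [blup_predict()], using the corresponding
#' sub-blocks of the full-sample kinship matrix (the kinship is computed
#' once, as the BLUP partition of the model implies). Prediction ability is
#' the Pearson correlation of observed and out-of-fold predicted values over
#' the whole sample, one value per replicate and trait. Traits are fitted
#' independently.
#'
#' @param K Kinship matrix for all phenotyped hybrids.
#' @param pheno Data frame with a `hybrid_id` column (matching the order of
#'   `K`'s rows when ids are absent from `K`) and one numeric column per
#'   trait.
#' @param k Folds per replicate (default 10).
#' @param replicates Number of independent partitions (default 10).
#' @param seed Integer seed (default 1).
#' @return An object of class `cv_result`: list with `folds` (replicate x
#'   individual labels), `predicted` (long tibble: trait, replicate,
#'   hybrid_id, y_obs, y_hat), `ability` (tibble: trait, replicate, ability)
#'   and `summary` (tibble: trait, ability_mean, ability_sd).
#' @export
cross_validate <- function(K, pheno, k = 10, replicates = 10, seed = 1) {
  K <- as_kinship(K)
  pheno <- as.data.frame(pheno)
  if (!"hybrid_id" %in% names(pheno)) {
    pheno <- cbind(hybrid_id = rownames(K) %||%
                     paste0("hyb", seq_len(nrow(pheno))), pheno)
  }
  traits <- setdiff(names(pheno), "hybrid_id")
  if (!length(traits)) stop("no trait columns in `pheno`.", call. = FALSE)
  if (!is.null(rownames(K)) && all(pheno$hybrid_id %in% rownames(K))) {
    K <- K[pheno$hybrid_id, pheno$hybrid_id]
  }
  n <- nrow(pheno)
  if (nrow(K) != n) stop("kinship and phenotypes are not aligned.",
                         call. = FALSE)
  folds <- matrix(NA_integer_, replicates, n)
  pred_rows <- list()
  ab_rows <- list()
  for (rep_i in seq_len(replicates)) {
    fold <- kfold_partition(n, k, seed + rep_i - 1)
    folds[rep_i, ] <- fold
    for (tr in traits) {
      y <- pheno[[tr]]
      y_hat <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        test <- which(fold == f)
        train <- which(fold != f)
        fit <- tryCatch(
          fit_reml(y[train], K[train, train, drop = FALSE]),
          error = function(e) NULL)
        if (is.null(fit)) {
          warning(sprintf(
            "REML failed in replicate %d fold %d (trait %s); fold skipped.",
            rep_i, f, tr), call. = FALSE)
          next
        }
        y_hat[test] <- blup_predict(fit, K[test, train, drop = FALSE])$y_hat
      }
      obs_ok <- !is.na(y_hat)
      pred_rows[[length(pred_rows) + 1]] <- tibble::tibble(
        trait = tr, replicate = rep_i, hybrid_id = pheno$hybrid_id,
        fold = fold, y_obs = y, y_hat = y_hat)
      ab_rows[[length(ab_rows) + 1]] <- tibble::tibble(
        trait = tr, replicate = rep_i,
        ability = prediction_ability(y[obs_ok], y_hat[obs_ok]))
    }
  }
  ability <- dplyr::bind_rows(ab_rows)
  summary <- dplyr::summarise(dplyr::group_by(ability, .data$trait),
                              ability_mean = mean(.data$ability),
                              ability_sd = stats::sd(.data$ability),
                              .groups = "drop")
  structure(list(folds = folds, predicted = dplyr::bind_rows(pred_rows),
                 ability = ability, summary = summary,
                 k = k, replicates = replicates, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d replicate(s)\n", x$k, x$replicates))
  print(x$summary)
  invisible(x)
}

#' Broad-sense heritability from a randomized complete block design
#'
#' Fits the two-way model y_jk = mu + alpha_j + beta_k + e_jk (hybrids j
#' random, blocks k fixed, no replication within cell) and estimates the
#' variance components by Henderson's expected-mean-squares method of
#' moments: MS_G = sigma2_E + b * sigma2_G over hybrids, so
#' sigma2_G = (MS_G - MS_E) / b with b the number of blocks. The broad-sense
#' heritability is h2 = sigma2_G / (sigma2_G + sigma2_E); a negative moment
#' estimate of sigma2_G is reported raw and truncated at zero for h2. A
#' REML alternative (profile over the hybrid variance with blocks fixed) is
#' available via `method = "reml"`.
#'
#' @param pheno Data frame with columns `hybrid_id`, `block`, `value` (or
#'   supply the column names via `hybrid`, `block`, `value`). Hybrids missing
#'   any block are dropped with a warning.
#' @param hybrid,block,value Column names in `pheno`.
#' @param method `"moments"` (default) or `"reml"`.
#' @return An object of class `variance_components`: list with `sigma2_G`,
#'   `sigma2_G_raw`, `sigma2_E`, `h2_broad`, `grand_mean`, `block_effects`,
#'   `n_hybrids`, `n_blocks` and the ANOVA `table` (source, df, mean square).
#' @export
fit_crbd <- function(pheno, hybrid = "hybrid_id", block = "block",
                     value = "value", method = c("moments", "reml")) {
  method <- match.arg(method)
  pheno <- as.data.frame(pheno)
  need <- c(hybrid, block, value)
  if (!all(need %in% names(pheno))) {
    stop(sprintf("`pheno` needs columns %s.", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df <- data.frame(hybrid = as.character(pheno[[hybrid]]),
                   block = as.character(pheno[[block]]),
                   value = as.numeric(pheno[[value]]))
  df <- df[!is.na(df$value), ]
  blocks <- sort(unique(df$block))
  b <- length(blocks)
  if (b < 2) stop("need at least two blocks to separate sigma2_E.",
                  call. = FALSE)
  counts <- table(df$hybrid)
  complete <- names(counts)[counts == b]
  if (length(complete) < length(counts)) {
    warning(sprintf("dropping %d hybrid(s) not observed in every block.",
                    length(counts) - length(complete)), call. = FALSE)
  }
  df <- df[df$hybrid %in% complete, ]
  n <- length(complete)
  if (n < 2) stop("fewer than two complete hybrids.", call. = FALSE)
  Y <- matrix(NA_real_, n, b, dimnames = list(sort(complete), blocks))
  Y[cbind(match(df$hybrid, rownames(Y)), match(df$block, blocks))] <- df$value

  grand <- mean(Y)
  hyb_means <- rowMeans(Y)
  blk_means <- colMeans(Y)
  ss_g <- b * sum((hyb_means - grand)^2)
  ss_b <- n * sum((blk_means - grand)^2)
  resid <- Y - outer(hyb_means, rep(1, b)) -
    outer(rep(1, n), blk_means) + grand
  ss_e <- sum(resid^2)
  ms_g <- ss_g / (n - 1)
  ms_b <- ss_b / (b - 1)
  ms_e <- ss_e / ((n - 1) * (b - 1))

  if (method == "moments") {
    sigma2_G_raw <- (ms_g - ms_e) / b
    sigma2_E <- ms_e
  } else {
    # REML with blocks fixed: eigen trick on the hybrid incidence structure
    y <- as.vector(Y)
    Xf <- kronecker(diag(b), matrix(1, n, 1))
    Kh <- kronecker(matrix(1, b, b), diag(n))  # var of hybrid effect
    fit <- fit_reml(y, Kh, Xf)
    sigma2_G_raw <- fit$phi2_hat
    sigma2_E <- fit$sigma2_hat
  }
  sigma2_G <- max(sigma2_G_raw, 0)
  h2 <- if (sigma2_G + sigma2_E > 0) sigma2_G / (sigma2_G + sigma2_E) else 0
  structure(list(
    sigma2_G = sigma2_G, sigma2_G_raw = sigma2_G_raw, sigma2_E = sigma2_E,
    h2_broad = h2, grand_mean = grand,
    block_effects = blk_means - grand,
    n_hybrids = n, n_blocks = b, method = method,
    table = tibble::tibble(
      source = c("hybrid", "block", "residual"),
      df = c(n - 1, b - 1, (n - 1) * (b - 1)),
      mean_square = c(ms_g, ms_b, ms_e),
      expected_mean_square = c(sprintf("sigma2_E + %d sigma2_G", b),
                               "sigma2_E + n sum(beta_k^2)/(b-1)",
                               "sigma2_E"))
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> randomized complete block design\n")
  cat(sprintf("  sigma2_G: %.6g (raw %.6g)  sigma2_E: %.6g\n",
              x$sigma2_G, x$sigma2_G_raw, x$sigma2_E))
  cat(sprintf("  broad-sense h2: %.4f  (%d hybrids, %d blocks)\n",
              x$h2_broad, x$n_hybrids, x$n_blocks))
  invisible(x)
}
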