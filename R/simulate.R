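#' Configuration for the synthetic hybrid-breeding generator
#'
#' Bundles the parameters of the simulated study system: a panel of inbred
#' parents genotyped at biallelic SNPs, crosses whose hybrid genotype is the
#' parental mean code, and polygenic phenotypes with configurable additive,
#' dominance and genotype-by-environment variance shares and a target
#' broad-sense heritability.
#'
#' @param n_parents Number of inbred parents (default 50).
#' @param m_markers Number of biallelic markers (default 500).
#' @param maf_low,maf_high Range of per-marker minor allele frequencies from
#'   which the parental allele frequency is drawn uniformly (defaults 0.1 and
#'   0.5, the post-filtering spectrum of a diversity panel).
#' @param residual_het_rate Probability that a parental call is heterozygous
#'   (default 0.01; inbred lines are occasionally residually heterozygous).
#' @param missing_rate Probability a parental call is missing (default 0).
#' @param h2_target Broad-sense heritability of the simulated phenotypes
#'   (default 0.5).
#' @param dominance_share,gxe_share Fractions of the genetic variance
#'   assigned to dominance and to environment-specific deviations (defaults
#'   0; their sum must be <= 1; the remainder is additive).
#' @param n_environments Number of environments (default 1).
#' @param n_qtl Number of markers with nonzero additive effect; `NULL`
#'   (default) makes the trait fully polygenic (every marker a QTL).
#' @param mu Grand mean of the phenotype (default 0, arbitrary trait units).
#' @param seed Integer seed (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 50, m_markers = 500,
                       maf_low = 0.1, maf_high = 0.5,
                       residual_het_rate = 0.01, missing_rate = 0,
                       h2_target = 0.5, dominance_share = 0, gxe_share = 0,
                       n_environments = 1, n_qtl = NULL, mu = 0, seed = 1) {
  cfg <- list(n_parents = n_parents, m_markers = m_markers,
              maf_low = maf_low, maf_high = maf_high,
              residual_het_rate = residual_het_rate,
              missing_rate = missing_rate,
              h2_target = h2_target, dominance_share = dominance_share,
              gxe_share = gxe_share, n_environments = n_environments,
              n_qtl = n_qtl, mu = mu, seed = seed)
  stopifnot(n_parents >= 2, m_markers >= 1,
            maf_low > 0, maf_high <= 0.5, maf_low <= maf_high,
            residual_het_rate >= 0, residual_het_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            h2_target >= 0, h2_target <= 1,
            dominance_share >= 0, gxe_share >= 0,
            dominance_share + gxe_share <= 1,
            n_environments >= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate genotypes of inbred parents
#'
#' Each marker draws an allele frequency uniformly from
#' `[maf_low, maf_high]`; each parent is then homozygous (code 1 with the
#' marker's allele frequency, else -1) unless a residual-heterozygosity event
#' (probability `residual_het_rate`) makes it 0. Calls are masked at
#' `missing_rate`. Markers are independent (the prediction machinery never
#' uses marker positions, so linkage is not modelled).
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] of dimension `m_markers x n_parents`.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    m <- config$m_markers
    n <- config$n_parents
    p <- stats::runif(m, config$maf_low, config$maf_high)
    codes <- matrix(ifelse(stats::runif(m * n) < p, 1, -1), m, n)
    if (config$residual_het_rate > 0) {
      codes[stats::runif(m * n) < config$residual_het_rate] <- 0
    }
    if (config$missing_rate > 0) {
      codes[stats::runif(m * n) < config$missing_rate] <- NA
    }
  })
  genotype_matrix(codes,
                  marker_ids = sprintf("mk%04d", seq_len(config$m_markers)),
                  individual_ids = sprintf("P%03d", seq_len(config$n_parents)))
}

#' Simulate polygenic phenotypes for a set of hybrids
#'
#' Marker additive effects are drawn iid normal (the polygenic assumption
#' behind GBLUP) and applied to the hybrid codes; optional dominance effects
#' act on the heterozygosity codes, and optional environment-specific marker
#' effects create genotype-by-environment deviations. Each realized genetic
#' component is rescaled to its requested variance share (empirical
#' calibration, robust to any dominance/G-x-E setting), the total genetic
#' variance is normalised to 1 trait unit squared, and the residual draw is
#' rescaled so the realized broad-sense heritability equals `h2_target`
#' exactly.
#'
#' @param hybrids A [genotype_matrix()] of the hybrids (no missing entries).
#' @param config A [sim_config()]; a separate `seed` can be given to decouple
#'   effect draws from parent simulation.
#' @param seed Optional seed override (default `config$seed + 1`).
#' @return List with `pheno` (tibble: hybrid_id, environment, value),
#'   `truth` (tibble: hybrid_id, environment, genetic_value, plus the
#'   environment-free columns `additive`, `dominance`) and the realized
#'   `h2`.
#' @export
simulate_phenotypes <- function(hybrids, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  Z <- unclass(as_genotype_matrix(hybrids))
  if (anyNA(Z)) stop("hybrid genotypes must be complete.", call. = FALSE)
  m <- nrow(Z); n <- ncol(Z)
  if (n < 2) stop("need at least two hybrids.", call. = FALSE)
  E <- config$n_environments
  add_share <- 1 - config$dominance_share - config$gxe_share
  no_qtl <- !is.null(config$n_qtl) && config$n_qtl == 0
  if (config$h2_target > 0 && no_qtl) {
    stop("no genetic variance requested (n_qtl = 0) but h2_target > 0.",
         call. = FALSE)
  }
  seed <- seed %||% (config$seed + 1)
  withr::with_seed(seed, {
    qtl <- if (is.null(config$n_qtl) || no_qtl) seq_len(m) else
      sample.int(m, min(config$n_qtl, m))
    gamma <- stats::rnorm(length(qtl))
    g_add <- drop(crossprod(Z[qtl, , drop = FALSE], gamma))
    g_add <- scale_to_var(g_add, add_share)
    g_dom <- 0
    if (config$dominance_share > 0) {
      W <- 1 - abs(2 * Z[qtl, , drop = FALSE])
      W[W < 0] <- 0
      delta <- stats::rnorm(length(qtl))
      g_dom <- scale_to_var(drop(crossprod(W, delta)),
                            config$dominance_share)
    }
    g_env <- matrix(0, n, E)
    if (config$gxe_share > 0) {
      for (e in seq_len(E)) {
        ge <- drop(crossprod(Z[qtl, , drop = FALSE],
                             stats::rnorm(length(qtl))))
        g_env[, e] <- scale_to_var(ge, config$gxe_share)
      }
    }
    genetic <- matrix(g_add + g_dom, n, E) + g_env   # var ~ 1 per env
    if (no_qtl) genetic[] <- 0
    h2 <- config$h2_target
    if (h2 == 0) genetic[] <- 0
    resid <- matrix(0, n, E)
    if (h2 < 1) {
      for (e in seq_len(E)) {
        # calibrate against the realized genetic variance of this environment
        vg_e <- stats::var(genetic[, e]) * (n - 1) / n
        target_ve <- if (h2 > 0) vg_e * (1 - h2) / h2 else 1
        resid[, e] <- scale_to_var(stats::rnorm(n), target_ve)
      }
    }
  })
  Yobs <- config$mu + genetic + resid
  ids <- colnames(Z)
  envs <- paste0("env", seq_len(E))
  pheno <- tibble::tibble(
    hybrid_id = rep(ids, E),
    environment = rep(envs, each = n),
    value = as.vector(Yobs))
  truth <- tibble::tibble(
    hybrid_id = rep(ids, E),
    environment = rep(envs, each = n),
    genetic_value = as.vector(genetic),
    additive = rep(g_add, E),
    dominance = rep(if (length(g_dom) == 1) rep(0, n) else g_dom, E))
  vg <- stats::var(as.vector(genetic))
  vr <- stats::var(as.vector(resid))
  structure(list(pheno = pheno, truth = truth,
                 h2 = if (vg + vr > 0) vg / (vg + vr) else 0),
            class = "sim_phenotypes")
}

# rescale a vector so its population variance equals `v` (no-op at v = 0)
scale_to_var <- function(x, v) {
  if (v <= 0) return(x * 0)
  s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  if (s == 0) stop("degenerate component with zero variance.", call. = FALSE)
  (x - mean(x)) / s * sqrt(v)
}

#' Build a complete training/test fixture
#'
#' End-to-end synthetic data mirroring the hybrid-prediction workflow: a
#' parental panel is simulated, crossed in a half diallel, and the resulting
#' hybrids are split into a phenotyped training population and an
#' unphenotyped test population whose true genetic values are retained for
#' oracle comparisons. Phenotypes for both sets are drawn jointly from the
#' same marker effects so training and test genetic values share their
#' covariance structure.
#'
#' @param config A [sim_config()].
#' @param n_train,n_test Sizes of the two hybrid sets.
#' @param design `"overlap"` (default; crosses sampled at random, so training
#'   and test hybrids share parents) or `"disjoint"` (the parent panel is
#'   split in two, training crosses use the first half only and test crosses
#'   the second half, emulating prediction of a genetically separate
#'   population).
#' @return List with `parents`, `hybrids` (genotype matrix of all sampled
#'   crosses), `train_ids`, `test_ids`, `pheno_train` and `pheno_test`
#'   (tibbles; test phenotypes are the would-be observations, retained for
#'   validation), `truth` (tibble for all hybrids), `K` (kinship over all
#'   hybrids) and the realized `h2`.
#' @export
make_training_and_test <- function(config, n_train = 200, n_test = 50,
                                   design = c("overlap", "disjoint")) {
  design <- match.arg(design)
  parents <- simulate_parents(config)
  ids <- colnames(parents)
  withr::with_seed(config$seed + 2, {
    if (design == "overlap") {
      panel <- parent_panel(ids, group = "A")
      crosses <- half_diallel(panel)
      if (nrow(crosses) < n_train + n_test) {
        stop("not enough crosses; increase n_parents.", call. = FALSE)
      }
      pick <- sample.int(nrow(crosses), n_train + n_test)
      train_cr <- crosses[pick[seq_len(n_train)], ]
      test_cr <- crosses[pick[n_train + seq_len(n_test)], ]
    } else {
      half <- floor(length(ids) / 2)
      pool1 <- half_diallel(parent_panel(ids[seq_len(half)], group = "A"))
      pool2 <- half_diallel(parent_panel(ids[-seq_len(half)], group = "A"))
      if (nrow(pool1) < n_train || nrow(pool2) < n_test) {
        stop("not enough crosses; increase n_parents.", call. = FALSE)
      }
      train_cr <- pool1[sample.int(nrow(pool1), n_train), ]
      test_cr <- pool2[sample.int(nrow(pool2), n_test), ]
    }
  })
  all_cr <- rbind(train_cr, test_cr)
  hybrids <- impute_mean(build_hybrid_matrix(parents,
                                             all_cr[c("parent1", "parent2")]))
  sim <- simulate_phenotypes(hybrids, config)
  train_ids <- hybrid_id(train_cr$parent1, train_cr$parent2)
  test_ids <- hybrid_id(test_cr$parent1, test_cr$parent2)
  K <- compute_kinship(hybrids)
  list(parents = parents, hybrids = hybrids,
       train_ids = train_ids, test_ids = test_ids,
       pheno_train = sim$pheno[sim$pheno$hybrid_id %in% train_ids, ],
       pheno_test = sim$pheno[sim$pheno$hybrid_id %in% test_ids, ],
       truth = sim$truth, K = K, h2 = sim$h2)
}
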