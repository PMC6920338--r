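test_that("hybrid codes are the parental mean and obey the coding rules", {
  # worked examples for each mating type
  expect_identical(deduce_hybrid_code(-1, 0), -0.5)
  expect_identical(deduce_hybrid_code(1, 0), 0.5)
  expect_identical(deduce_hybrid_code(0, 0), 0)
  expect_identical(deduce_hybrid_code(-1, -1), -1)
  expect_identical(deduce_hybrid_code(-1, 1), 0)
  # symmetry and self-reproduction over all parental code pairs
  codes <- c(-1, 0, 1)
  for (a in codes) for (b in codes) {
    expect_identical(deduce_hybrid_code(a, b), deduce_hybrid_code(b, a))
    expect_true(deduce_hybrid_code(a, b) %in% c(-1, -0.5, 0, 0.5, 1))
  }
  for (a in c(-1, 1)) expect_identical(deduce_hybrid_code(a, a), a)
  # missing propagates; invalid codes rejected
  expect_true(is.na(deduce_hybrid_code(NA, 1)))
  expect_error(deduce_hybrid_code(2, 0), "invalid genotype")
  expect_error(deduce_hybrid_code(-0.5, 0), "invalid genotype")
})

test_that("build_hybrid_matrix deduces crosses marker-wise", {
  P <- genotype_matrix(matrix(c(-1, 1, 1, 1, -1, -1), 2, 3),
                       marker_ids = c("m1", "m2"),
                       individual_ids = c("P1", "P2", "P3"))
  H <- build_hybrid_matrix(P, data.frame(p1 = "P1", p2 = "P2"))
  expect_equal(unname(unclass(H)[, 1]), c(0, 1))
  expect_identical(colnames(H), "P1_x_P2")
  # half diallel of 3 parents -> choose(3,2) hybrids
  cr <- half_diallel(parent_panel(c("P1", "P2", "P3"), group = "g"))
  H3 <- build_hybrid_matrix(P, cr[c("parent1", "parent2")])
  expect_identical(ncol(H3), 3L)
  # reciprocal crosses collapse to one column
  expect_warning(
    Hd <- build_hybrid_matrix(P, data.frame(p1 = c("P1", "P2"),
                                            p2 = c("P2", "P1"))),
    "duplicate")
  expect_identical(ncol(Hd), 1L)
  expect_error(build_hybrid_matrix(P, data.frame(p1 = "P1", p2 = "PX")),
               "unknown parent")
  # missing parent call makes the hybrid call missing
  Pm <- genotype_matrix(matrix(c(NA, 1, 1, -1), 2, 2),
                        individual_ids = c("A", "B"))
  Hm <- build_hybrid_matrix(Pm, data.frame(p1 = "A", p2 = "B"))
  expect_true(is.na(unclass(Hm)[1, 1]))
  expect_identical(unname(unclass(Hm)[2, 1]), 0)
})

test_that("marker filtering applies strict MAF and non-strict missingness", {
  # MAF 1/6 > 0.1 is kept
  g1 <- c(-1, -1, -1, -1, -1, 1)
  # 2/6 missing > 25% removed; monomorphic removed; common marker kept
  codes <- rbind(g1,
                 c(-1, 1, NA, NA, -1, 1),
                 c(-1, -1, -1, -1, -1, -1),
                 c(-1, 1, -1, 1, -1, 1))
  G <- genotype_matrix(codes, marker_ids = paste0("m", 1:4))
  out <- filter_markers(G, maf_min = 0.1, missing_max = 0.25)
  expect_identical(rownames(out), c("m1", "m4"))
  rep <- filter_report(out)
  expect_identical(rep$n_markers[rep$criterion == "missingness"], 1L)
  expect_identical(rep$n_markers[rep$criterion == "maf"], 1L)
  expect_identical(rep$n_markers[rep$criterion == "kept"], 2L)
  # idempotence: refiltering removes nothing
  again <- filter_markers(out, maf_min = 0.1, missing_max = 0.25)
  expect_equal(unclass(again), unclass(out), ignore_attr = TRUE)
  expect_identical(rownames(again), rownames(out))
  # monomorphic marker fails any maf_min >= 0
  mono <- genotype_matrix(matrix(-1, 1, 6))
  expect_error(filter_markers(mono, maf_min = 0), "all markers removed")
  # exact threshold: 25% missing is retained (non-strict)
  at25 <- genotype_matrix(rbind(c(-1, 1, NA, 1), c(1, -1, 1, -1)))
  expect_identical(nrow(filter_markers(at25, missing_max = 0.25)), 2L)
})

test_that("mean imputation fills missing calls with the marker mean", {
  G <- genotype_matrix(rbind(c(-1, 1, NA), c(1, 1, NA), c(-1, 0, 1)))
  out <- impute_mean(G)
  expect_false(anyNA(out))
  expect_equal(unname(unclass(out)[1, 3]), 0)
  expect_equal(unname(unclass(out)[2, 3]), 1)
  # no missing input -> identity
  G2 <- genotype_matrix(rbind(c(-1, 1, 0)))
  expect_equal(unclass(impute_mean(G2)), unclass(G2))
  expect_error(impute_mean(genotype_matrix(rbind(c(NA_real_, NA_real_)))),
               "entirely missing")
})

test_that("additive kinship equals the scaled sum of marker outer products", {
  # single marker, codes (1, -1)
  K1 <- compute_kinship(genotype_matrix(matrix(c(1, -1), 1, 2)))
  expect_equal(unclass(K1), matrix(c(1, -1, -1, 1), 2, 2),
               ignore_attr = TRUE)
  # all-zero codes give the zero matrix
  K0 <- compute_kinship(genotype_matrix(matrix(0, 3, 4)))
  expect_true(all(K0 == 0))
  # brute-force oracle on a random panel
  withr::with_seed(11, {
    Z <- matrix(sample(c(-1, -0.5, 0, 0.5, 1), 200, replace = TRUE), 20, 10)
  })
  K <- compute_kinship(genotype_matrix(Z))
  expect_equal(unclass(K), brute_kinship(Z), ignore_attr = TRUE,
               tolerance = 1e-12)
  # symmetric PSD
  expect_equal(unclass(K), t(unclass(K)), ignore_attr = TRUE)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  # column permutation permutes K accordingly
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  Kp <- compute_kinship(genotype_matrix(Z[, perm]))
  expect_equal(unclass(Kp), unclass(K)[perm, perm], ignore_attr = TRUE)
  # linearity: K over m markers is the mean of single-marker K's
  withr::with_seed(12, {
    Z5 <- matrix(sample(c(-1, 0, 1), 40, replace = TRUE), 5, 8)
  })
  Ks <- lapply(1:5, function(k)
    unclass(compute_kinship(genotype_matrix(Z5[k, , drop = FALSE]))))
  expect_equal(unclass(compute_kinship(genotype_matrix(Z5))),
               Reduce(`+`, Ks) / 5, ignore_attr = TRUE)
  expect_error(compute_kinship(genotype_matrix(matrix(c(NA, 1), 1, 2))),
               "missing")
})

test_that("dominance kinship is built from heterozygosity codes", {
  # heterozygote -> 1, homozygote -> 0
  KD <- compute_dominance_kinship(genotype_matrix(matrix(c(0, 1), 1, 2)))
  expect_equal(unclass(KD), matrix(c(1, 0, 0, 0), 2, 2), ignore_attr = TRUE)
  # fully homozygous panel has zero dominance relationship
  KD0 <- compute_dominance_kinship(
    genotype_matrix(matrix(c(-1, 1, 1, -1), 2, 2)))
  expect_true(all(KD0 == 0))
  # half codes map to expected heterozygosity 0.5; brute-force oracle
  withr::with_seed(13, {
    Z <- matrix(sample(c(-1, -0.5, 0, 0.5, 1), 120, replace = TRUE), 12, 10)
  })
  W <- 1 - abs(2 * Z)
  W[W < 0] <- 0
  expect_equal(unclass(compute_dominance_kinship(genotype_matrix(Z))),
               brute_kinship(W), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("VanRaden-centered kinship is available behind a flag", {
  withr::with_seed(14, {
    Z <- matrix(sample(c(-1, 1), 200, replace = TRUE), 20, 10)
  })
  K <- compute_kinship(genotype_matrix(Z), method = "vanraden")
  p <- (rowMeans(Z) + 1) / 2
  Zc <- Z - (2 * p - 1)
  expect_equal(unclass(K), crossprod(Zc) / (2 * sum(p * (1 - p))),
               ignore_attr = TRUE)
})
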