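test_that("simulated parents honour the configured code set and MAF range", {
  cfg <- sim_config(n_parents = 60, m_markers = 200, residual_het_rate = 0,
                    missing_rate = 0.05, seed = 3)
  P <- simulate_parents(cfg)
  vals <- unique(as.vector(unclass(P)))
  expect_true(all(vals[!is.na(vals)] %in% c(-1, 1)))
  expect_gt(sum(is.na(P)), 0)
  # same seed reproduces bit-identical output
  expect_identical(unclass(simulate_parents(cfg)), unclass(P))
  # residual heterozygosity introduces zeros
  cfg2 <- sim_config(n_parents = 60, m_markers = 200,
                     residual_het_rate = 0.2, seed = 3)
  expect_gt(sum(simulate_parents(cfg2) == 0, na.rm = TRUE), 0)
  # fixed maf 0.5 centers the codes
  cfg3 <- sim_config(n_parents = 400, m_markers = 50, maf_low = 0.5,
                     maf_high = 0.5, seed = 4)
  P3 <- simulate_parents(cfg3)
  expect_lt(max(abs(rowMeans(P3))), 3 / sqrt(400))
  # realized frequencies stay inside the configured band up to noise
  cfg4 <- sim_config(n_parents = 500, m_markers = 100, maf_low = 0.2,
                     maf_high = 0.4, seed = 5)
  p <- (rowMeans(simulate_parents(cfg4)) + 1) / 2
  maf <- pmin(p, 1 - p)
  expect_gt(min(maf), 0.2 - 4 * sqrt(0.25 / 500))
})

test_that("phenotype simulation calibrates heritability exactly", {
  cfg <- sim_config(n_parents = 30, m_markers = 150, h2_target = 1, seed = 6)
  P <- simulate_parents(cfg)
  H <- build_hybrid_matrix(P, half_diallel(parent_panel(colnames(P),
                                                        "g"))[2:3])
  sim <- simulate_phenotypes(H, cfg)
  expect_equal(sim$pheno$value - cfg$mu, sim$truth$genetic_value,
               tolerance = 1e-12)
  expect_equal(sim$h2, 1)
  # h2 = 0.5: realized ratio is exact by construction
  cfg5 <- sim_config(n_parents = 30, m_markers = 150, h2_target = 0.5,
                     seed = 7)
  sim5 <- simulate_phenotypes(H, cfg5)
  expect_equal(sim5$h2, 0.5, tolerance = 1e-10)
  # variance decomposition honours requested shares
  cfgd <- sim_config(n_parents = 30, m_markers = 150, h2_target = 0.8,
                     dominance_share = 0.3, residual_het_rate = 0.1,
                     seed = 8)
  Hd <- build_hybrid_matrix(simulate_parents(cfgd),
                            half_diallel(parent_panel(colnames(P), "g"))[2:3])
  simd <- simulate_phenotypes(Hd, cfgd)
  n <- length(unique(simd$truth$hybrid_id))
  vd <- stats::var(simd$truth$dominance[1:n]) * (n - 1) / n
  va <- stats::var(simd$truth$additive[1:n]) * (n - 1) / n
  expect_equal(vd, 0.3, tolerance = 1e-8)
  expect_equal(va, 0.7, tolerance = 1e-8)
  # no G x E requested: genetic values identical across environments
  cfge <- sim_config(n_parents = 30, m_markers = 150, gxe_share = 0,
                     n_environments = 2, seed = 9)
  sime <- simulate_phenotypes(H, cfge)
  g1 <- sime$truth$genetic_value[sime$truth$environment == "env1"]
  g2 <- sime$truth$genetic_value[sime$truth$environment == "env2"]
  expect_equal(stats::cor(g1, g2), 1)
  # requesting heritability without genetic variance is an error
  cfg0 <- sim_config(n_parents = 30, m_markers = 150, h2_target = 0.5,
                     n_qtl = 0, seed = 10)
  expect_error(simulate_phenotypes(H, cfg0), "no genetic variance")
})

test_that("training/test bundles support end-to-end prediction checks", {
  # disjoint parents: only identity-by-state relatedness carries signal, so
  # transfer is weak but positive on average
  rs <- vapply(1:6, function(s) {
    cfg <- sim_config(n_parents = 60, m_markers = 600, h2_target = 0.8,
                      seed = 700 + s)
    b <- make_training_and_test(cfg, n_train = 350, n_test = 60,
                                design = "disjoint")
    y <- b$pheno_train$value[match(b$train_ids, b$pheno_train$hybrid_id)]
    fit <- fit_reml(y, b$K[b$train_ids, b$train_ids])
    pred <- blup_predict(fit, b$K[b$test_ids, b$train_ids])
    truth <- b$truth$genetic_value[match(b$test_ids, b$truth$hybrid_id)]
    stats::cor(pred$y_hat, truth)
  }, numeric(1))
  expect_gt(mean(rs), 0)
  # shared parents: strong transfer at high heritability
  rs2 <- vapply(1:3, function(s) {
    cfg <- sim_config(n_parents = 40, m_markers = 300, h2_target = 0.8,
                      seed = 700 + s)
    b <- make_training_and_test(cfg, n_train = 150, n_test = 40)
    y <- b$pheno_train$value[match(b$train_ids, b$pheno_train$hybrid_id)]
    fit <- fit_reml(y, b$K[b$train_ids, b$train_ids])
    pred <- blup_predict(fit, b$K[b$test_ids, b$train_ids])
    truth <- b$truth$genetic_value[match(b$test_ids, b$truth$hybrid_id)]
    stats::cor(pred$y_hat, truth)
  }, numeric(1))
  expect_gt(min(rs2), 0.8)
  # null config: ability against the held-out phenotypes centred on zero
  r0 <- vapply(1:5, function(s) {
    cfg <- sim_config(n_parents = 40, m_markers = 300, h2_target = 0,
                      seed = 800 + s)
    b <- make_training_and_test(cfg, n_train = 150, n_test = 40)
    y <- b$pheno_train$value[match(b$train_ids, b$pheno_train$hybrid_id)]
    fit <- fit_reml(y, b$K[b$train_ids, b$train_ids])
    pred <- blup_predict(fit, b$K[b$test_ids, b$train_ids])
    obs <- b$pheno_test$value[match(b$test_ids, b$pheno_test$hybrid_id)]
    if (stats::sd(pred$y_hat) == 0) 0 else stats::cor(pred$y_hat, obs)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.2)
  # determinism of the full bundle
  cfg <- sim_config(n_parents = 30, m_markers = 100, seed = 11)
  b1 <- make_training_and_test(cfg, n_train = 50, n_test = 10)
  b2 <- make_training_and_test(cfg, n_train = 50, n_test = 10)
  expect_identical(b1$train_ids, b2$train_ids)
  expect_identical(unclass(b1$hybrids), unclass(b2$hybrids))
  expect_identical(b1$pheno_train$value, b2$pheno_train$value)
})
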