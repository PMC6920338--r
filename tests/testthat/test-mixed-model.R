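test_that("eigendecomposition reconstructs the kinship matrix", {
  e <- eigendecompose(diag(3))
  expect_equal(e$values, rep(1, 3))
  e2 <- eigendecompose(matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(e2$values, c(2, 0))
  withr::with_seed(5, {
    Z <- matrix(sample(c(-1, 0, 1), 300, replace = TRUE), 30, 10)
  })
  K <- compute_kinship(genotype_matrix(Z))
  e3 <- eigendecompose(K)
  rec <- e3$vectors %*% (t(e3$vectors) * e3$values)
  expect_lt(max(abs(rec - unclass(K))), 1e-8)
  expect_gte(min(e3$values), 0)
  expect_error(eigendecompose(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("rotated restricted likelihood equals the dense evaluation", {
  for (seed in 1:10) {
    inst <- rand_instance(n = 12 + seed %% 8, m = 30, seed = seed,
                          q_extra = seed %% 2)
    eig <- eigendecompose(inst$K)
    for (lam in c(0, 0.1, 1, 10)) {
      expect_equal(
        restricted_loglik(lam, inst$y, X = inst$X, eig = eig),
        dense_restricted_loglik(lam, inst$y, inst$K, inst$X),
        tolerance = 1e-8)
    }
  }
})

test_that("at lambda = 0 the restricted likelihood is the OLS restricted fit", {
  inst <- rand_instance(n = 15, m = 25, seed = 3)
  n <- length(inst$y)
  q <- ncol(inst$X)
  fitlm <- stats::lm.fit(inst$X, inst$y)
  s2 <- sum(fitlm$residuals^2) / (n - q)
  ll_ols <- -0.5 * n * log(s2) -
    0.5 * determinant(crossprod(inst$X) / s2, logarithm = TRUE)$modulus[1] -
    (n - q) / 2
  expect_equal(restricted_loglik(0, inst$y, inst$K, inst$X), drop(ll_ols),
               tolerance = 1e-8)
})

test_that("Newton REML agrees with grid search and recovers lambda", {
  # optimizer equivalence on random instances
  for (seed in 1:8) {
    inst <- rand_instance(n = 60, m = 120, lambda = 2, seed = seed)
    fit <- fit_reml(inst$y, inst$K, inst$X)
    lam_grid <- grid_search_lambda(inst$y, inst$K, inst$X)
    expect_true(fit$converged)
    expect_lt(abs(fit$lambda_hat - lam_grid) / max(lam_grid, 1e-8), 1e-3)
    expect_equal(fit$phi2_hat, fit$lambda_hat * fit$sigma2_hat)
  }
  # pure-noise data drive lambda to the boundary
  lam0 <- vapply(1:10, function(s) {
    inst <- rand_instance(n = 100, m = 150, lambda = 0, seed = 100 + s)
    fit_reml(inst$y, inst$K)$lambda_hat
  }, numeric(1))
  expect_lt(stats::median(lam0), 0.1)
  # signal data recover the generating ratio within a broad band
  lam2 <- vapply(1:8, function(s) {
    inst <- rand_instance(n = 150, m = 300, lambda = 2, seed = 200 + s)
    fit_reml(inst$y, inst$K)$lambda_hat
  }, numeric(1))
  med <- stats::median(lam2)
  expect_gt(med, 0.5)
  expect_lt(med, 8)
})

test_that("degenerate constant phenotype is flagged", {
  K <- compute_kinship(genotype_matrix(
    matrix(sample(c(-1, 1), 50, replace = TRUE), 10, 5)))
  expect_warning(fit <- fit_reml(rep(2, 5), K), "constant")
  expect_lt(fit$sigma2_hat, 1e-12)
})

test_that("BLUP prediction matches the dense partitioned solve", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      Z <- matrix(sample(c(-1, 0, 1), 40 * 20, replace = TRUE), 40, 20)
    })
    K <- compute_kinship(genotype_matrix(Z))
    tr <- 1:15; te <- 16:20
    inst_y <- withr::with_seed(seed, {
      drop(crossprod(Z, rnorm(40, 0, 0.2))) + rnorm(20)
    })
    fit <- fit_reml(inst_y[tr], K[tr, tr])
    pred <- blup_predict(fit, K[te, tr])
    oracle <- dense_blup(fit$lambda_hat, fit$beta_hat, inst_y[tr],
                         fit$X, K[tr, tr], K[te, tr],
                         matrix(1, 5, 1))
    expect_equal(pred$y_hat, oracle, tolerance = 1e-10)
  }
})

test_that("BLUP has the no-signal and permutation-invariance properties", {
  inst <- rand_instance(n = 20, m = 30, lambda = 1, seed = 9)
  fit <- fit_reml(inst$y, inst$K)
  # lambda = 0 predicts the fixed-effect mean everywhere
  fit0 <- fit
  fit0$lambda_hat <- 0
  p0 <- blup_predict(fit0, matrix(rnorm(5 * 20), 5, 20))
  expect_equal(p0$y_hat, rep(fit$beta_hat, 5))
  # permuting training individuals leaves predictions unchanged
  K21 <- unclass(inst$K)[1:4, , drop = FALSE]
  p1 <- blup_predict(fit, K21)
  perm <- withr::with_seed(10, sample(20))
  fitp <- fit_reml(inst$y[perm], inst$K[perm, perm])
  p2 <- blup_predict(fitp, K21[, perm, drop = FALSE])
  expect_equal(p1$y_hat, p2$y_hat, tolerance = 1e-6)
  # in-sample prediction correlates with the data
  pin <- blup_predict(fit, inst$K)
  expect_gt(stats::cor(pin$y_hat, inst$y), 0)
})

test_that("A-D model nests the additive model and detects dominance", {
  withr::with_seed(21, {
    Z <- matrix(sample(c(-1, 0, 1), 80 * 60, replace = TRUE,
                       prob = c(0.4, 0.2, 0.4)), 80, 60)
  })
  G <- genotype_matrix(Z)
  K <- compute_kinship(G)
  KD <- compute_dominance_kinship(G)
  y <- withr::with_seed(21, drop(crossprod(Z, rnorm(80, 0, 0.15))) + rnorm(60))
  add <- fit_reml(y, K)
  # zero dominance kernel reproduces the additive fit exactly
  ad0 <- fit_ad_model(y, K, matrix(0, 60, 60))
  expect_equal(ad0$restricted_loglik, add$restricted_loglik,
               tolerance = 1e-10)
  expect_identical(ad0$lambda_d, 0)
  expect_equal(ad0$lambda_a, add$lambda_hat, tolerance = 1e-10)
  # the two-kernel optimum cannot be worse than the nested additive optimum
  ad <- fit_ad_model(y, K, KD)
  expect_gte(ad$restricted_loglik, add$restricted_loglik - 1e-8)
  # profiled likelihood agrees with an independent dense evaluation
  V0 <- unclass(K) * 0.6 + unclass(KD) * 0.4 + diag(60)
  expect_equal(ad_restricted_loglik(0.6, 0.4, y, K, KD),
               dense_restricted_loglik(1, y, V0 - diag(60),
                                       matrix(1, 60, 1)),
               tolerance = 1e-8)
})

test_that("A-D lambda_A tracks the additive fit when dominance is absent", {
  ratio <- vapply(1:6, function(s) {
    cfg <- sim_config(n_parents = 40, m_markers = 200, h2_target = 0.6,
                      residual_het_rate = 0.05, seed = 300 + s)
    b <- make_training_and_test(cfg, n_train = 120, n_test = 2)
    y <- b$pheno_train$value[match(b$train_ids, b$pheno_train$hybrid_id)]
    K <- b$K[b$train_ids, b$train_ids]
    KD <- compute_dominance_kinship(b$hybrids)[b$train_ids, b$train_ids]
    add <- fit_reml(y, K)
    ad <- fit_ad_model(y, K, KD)
    ad$lambda_a / max(add$lambda_hat, 1e-8)
  }, numeric(1))
  expect_lt(abs(stats::median(ratio) - 1), 0.2)
})

test_that("G x E model nests the additive model and matches dense algebra", {
  withr::with_seed(31, {
    Z <- matrix(sample(c(-1, 0, 1), 30 * 10, replace = TRUE), 30, 10)
    y <- rnorm(10)
  })
  K <- compute_kinship(genotype_matrix(Z))
  add <- fit_reml(y, K)
  g1 <- fit_gxe_model(matrix(y, ncol = 1), K)
  expect_equal(g1$restricted_loglik, add$restricted_loglik,
               tolerance = 1e-10)
  expect_identical(g1$lambda_gxe, 0)
  # dense Kronecker oracle for the stacked likelihood (n = 10, E = 2)
  Y <- cbind(y, y + withr::with_seed(32, rnorm(10, 0, 0.5)))
  for (lams in list(c(0.5, 0.3), c(2, 0.01), c(0.1, 1))) {
    KJ <- kronecker(matrix(1, 2, 2), unclass(K))
    KI <- kronecker(diag(2), unclass(K))
    V0 <- KJ * lams[1] + KI * lams[2]
    X <- kronecker(diag(2), matrix(1, 10, 1))
    expect_equal(gxe_restricted_loglik(lams[1], lams[2], Y, K),
                 dense_restricted_loglik(1, as.vector(Y), V0, X),
                 tolerance = 1e-8)
  }
  # identical phenotypes across environments leave no interaction variance
  gsame <- fit_gxe_model(cbind(y, y), K)
  expect_lt(gsame$lambda_gxe, 1e-6)
})

test_that("G x E predictions approach pooled additive ones without G x E", {
  cors <- vapply(1:4, function(s) {
    cfg <- sim_config(n_parents = 40, m_markers = 200, h2_target = 0.6,
                      gxe_share = 0, n_environments = 2, seed = 400 + s)
    b <- make_training_and_test(cfg, n_train = 120, n_test = 30)
    ph <- b$pheno_train
    Y <- cbind(ph$value[ph$environment == "env1"][
                 match(b$train_ids,
                       ph$hybrid_id[ph$environment == "env1"])],
               ph$value[ph$environment == "env2"][
                 match(b$train_ids,
                       ph$hybrid_id[ph$environment == "env2"])])
    K11 <- b$K[b$train_ids, b$train_ids]
    K21 <- b$K[b$test_ids, b$train_ids]
    gfit <- fit_gxe_model(Y, K11)
    pred_e1 <- blup_predict_gxe(gfit, K21)
    pred_e1 <- pred_e1$y_hat[pred_e1$environment == "env1"]
    pooled <- blup_predict(fit_reml(rowMeans(Y), K11), K21)$y_hat
    stats::cor(pred_e1, pooled)
  }, numeric(1))
  expect_gt(mean(cors), 0.95)
})
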