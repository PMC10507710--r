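# REML kernel mixed models and the two Gibbs samplers

test_that("fit_gblup recovers the noiseless and null limits", {
  sim <- quick_sim(2001, n = 150, m_per = 40)
  G <- grm_vanraden(snp_design(sim$gm, sim$map))
  # noiseless: y = G w exactly
  set.seed(5)
  y0 <- as.numeric(G$values %*% rnorm(150))
  f0 <- fit_gblup(y0, sim$X, G)
  expect_lt(f0$varcomp["residual"] / f0$varcomp[1], 1e-4)
  expect_gt(cor(f0$fitted, y0), 0.999)
  # null: y independent of G
  low <- sapply(1:20, function(s) {
    set.seed(6000 + s)
    yn <- rnorm(150)
    f <- fit_gblup(yn, sim$X, G)
    unname(f$varcomp[1] / (f$varcomp[1] + f$varcomp["residual"]))
  })
  expect_gte(sum(low < 0.1), 18)
})

test_that("REML is scale-equivariant and locally optimal", {
  sim <- quick_sim(2002, n = 100, m_per = 30, h2 = 0.5)
  G <- grm_vanraden(snp_design(sim$gm, sim$map))
  f1 <- fit_gblup(sim$y, sim$X, G)
  f2 <- fit_gblup(2 * sim$y, sim$X, G)
  expect_equal(unname(f2$varcomp), unname(4 * f1$varcomp), tolerance = 1e-6)
  expect_equal(f2$fitted, 2 * f1$fitted, tolerance = 1e-6)
  # optimum beats 10 random variance points
  set.seed(11)
  for (k in 1:10) {
    vc <- f1$varcomp * exp(runif(2, -1.5, 1.5))
    expect_gte(f1$reml_loglik + 1e-6, reml_loglik(sim$y, sim$X, G, vc))
  }
  # multi-kernel path too
  fe <- fit_egblup(sim$y, sim$X, G)
  fe2 <- fit_egblup(2 * sim$y, sim$X, G)
  expect_equal(unname(fe2$varcomp), unname(4 * fe$varcomp), tolerance = 1e-4)
  set.seed(12)
  for (k in 1:5) {
    vc <- pmax(fe$varcomp, 1e-6) * exp(runif(3, -1, 1))
    expect_gte(fe$reml_loglik + 1e-6,
               reml_loglik(sim$y, sim$X, list(G, epistatic_grm(G)), vc))
  }
})

test_that("fit_gblup validates its inputs", {
  sim <- quick_sim(2003, n = 50, m_per = 20)
  G <- grm_vanraden(snp_design(sim$gm, sim$map))
  expect_error(fit_gblup(replace(sim$y, 1, NA), sim$X, G), "complete")
  Xbad <- cbind(sim$X, sim$X[, 1])
  expect_error(fit_gblup(sim$y, Xbad, G), "rank")
})

test_that("fit_egblup partitions additive and epistatic signal", {
  res <- sapply(1:20, function(s) {
    sim <- quick_sim(2100 + s, n = 120, m_per = 30, h2 = 0.6)
    G <- grm_vanraden(snp_design(sim$gm, sim$map))
    f <- fit_egblup(sim$y, sim$X, G)
    # purely additive truth: epistatic share should stay small
    add <- unname(f$varcomp[2] / (f$varcomp[1] + f$varcomp[2] + 1e-12))
    # epistatic truth on the same panel
    set.seed(s)
    Gaa <- epistatic_grm(G)
    ye <- as.numeric(t(chol(hapblockr:::.jitter(Gaa$values))) %*% rnorm(120)) +
      rnorm(120, 0, 0.3)
    fe <- fit_egblup(ye, sim$X, G)
    epi <- unname(fe$varcomp[2] / (fe$varcomp[1] + fe$varcomp[2] + 1e-12))
    c(add_share = add, epi_share = epi)
  })
  expect_lt(median(res["add_share", ]), 0.2)
  expect_gt(median(res["epi_share", ]), 0.5)
})

test_that("fixing the epistatic variance at zero reduces EGBLUP to GBLUP", {
  sim <- quick_sim(2004, n = 80, m_per = 25)
  G <- grm_vanraden(snp_design(sim$gm, sim$map))
  fg <- fit_gblup(sim$y, sim$X, G)
  f0 <- fit_egblup(sim$y, sim$X, G, fixed = c(NA, 0))
  expect_equal(unname(f0$varcomp[c(1, 3)]), unname(fg$varcomp), tolerance = 1e-6)
  expect_equal(unname(f0$varcomp[2]), 0)
  expect_equal(f0$fitted, fg$fitted, tolerance = 1e-6)
})

test_that("predict extends BLUPs consistently", {
  sim <- quick_sim(2005, n = 120, m_per = 30, h2 = 0.6)
  Gall <- grm_vanraden(snp_design(sim$gm, sim$map))
  tr <- 1:70; te <- 71:120
  Gtr <- kernel_matrix(Gall$values[tr, tr], Gall$sample_ids[tr], "additive")
  f <- fit_gblup(sim$y[tr], sim$X[tr, , drop = FALSE], Gtr)
  pred <- predict(f, Gall$values[te, tr], sim$X[te, , drop = FALSE])
  # oracle: Henderson mixed-model equations on the training block, BLUPs
  # extended through the full kernel
  K <- hapblockr:::.jitter(Gall$values)
  lam <- unname(f$varcomp["residual"] / f$varcomp[1])
  Xtr <- sim$X[tr, , drop = FALSE]
  Kinv <- solve(K[tr, tr])
  lhs <- rbind(cbind(crossprod(Xtr), t(Xtr)),
               cbind(Xtr, diag(70) + lam * Kinv))
  rhs <- c(crossprod(Xtr, sim$y[tr]), sim$y[tr])
  sol <- solve(lhs, rhs)
  u_tr <- sol[-seq_len(ncol(Xtr))]
  pred_mme <- sim$X[te, , drop = FALSE] %*% sol[seq_len(ncol(Xtr))] +
    K[te, tr] %*% Kinv %*% u_tr
  expect_equal(pred, as.numeric(pred_mme), tolerance = 1e-4)
  # duplicating a training sample reproduces its fitted value
  pred_dup <- predict(f, Gall$values[tr[3], tr, drop = FALSE],
                      sim$X[tr[3], , drop = FALSE])
  expect_equal(pred_dup, f$fitted[3], tolerance = 1e-8)
  expect_error(predict(f, Gall$values[te, te], sim$X[te, , drop = FALSE]),
               "columns")
})

test_that("Bayesian LASSO: constant-y, single-marker and seed behavior", {
  n <- 60
  set.seed(3)
  M <- matrix(rbinom(n * 4, 2, 0.5), n, 4)
  X <- matrix(1, n, 1)
  fc <- fit_bayesian_lasso(rep(5, n) + rnorm(n, 0, 1e-8), X, M,
                           n_iter = 1500, burn_in = 500, seed = 1)
  expect_true(all(abs(fc$posterior$effects) < 0.01))
  # y = 2 * dosage + tiny noise
  y1 <- 2 * M[, 2] + rnorm(n, 0, 0.01)
  f1 <- fit_bayesian_lasso(y1, X, M[, 2, drop = FALSE],
                           n_iter = 2000, burn_in = 500, seed = 2)
  expect_lt(abs(f1$posterior$effects[1] - 2) / 2, 0.1)
  # seed reproducibility
  fa <- fit_bayesian_lasso(y1, X, M, n_iter = 800, burn_in = 200, seed = 9)
  fb <- fit_bayesian_lasso(y1, X, M, n_iter = 800, burn_in = 200, seed = 9)
  expect_identical(fa$posterior$effects, fb$posterior$effects)
  expect_error(fit_bayesian_lasso(y1, X, M, n_iter = 100, burn_in = 200, seed = 1),
               "burn_in")
})

test_that("RKHS: flat kernel yields no genetic structure; duplicates alias", {
  n <- 60
  set.seed(4)
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  ones <- kernel_matrix(matrix(1, n, n) + diag(1e-6, n), paste0("s", 1:n),
                        "gaussian")
  f <- fit_rkhs(y - mean(y), X, ones, n_iter = 1500, burn_in = 500, seed = 3)
  expect_lt(sd(f$posterior$genetic_values), 0.15 * sd(y))
  # duplicated kernels split variance but keep total genetic values
  sim <- quick_sim(2006, n = 80, m_per = 25, h2 = 0.6)
  G <- grm_vanraden(snp_design(sim$gm, sim$map))
  f1 <- fit_rkhs(sim$y, sim$X, G, n_iter = 2500, burn_in = 500, seed = 4)
  f2 <- fit_rkhs(sim$y, sim$X, list(G, G), n_iter = 2500, burn_in = 500, seed = 5)
  expect_gte(cor(f1$posterior$genetic_values, f2$posterior$genetic_values), 0.98)
})

test_that("all four models rank a noiseless additive toy identically", {
  sim <- quick_sim(2007, n = 100, m_per = 25, h2 = 1, qtl = 20)
  des <- snp_design(sim$gm, sim$map)
  G <- grm_vanraden(des)
  y <- sim$y
  fg <- fit_gblup(y, sim$X, G)
  fe <- fit_egblup(y, sim$X, G)
  M <- sweep(des$Z, 2, -2 * des$freqs)
  fb <- fit_bayesian_lasso(y, sim$X, M, n_iter = 2500, burn_in = 500, seed = 6)
  fr <- fit_rkhs(y, sim$X, gaussian_kernels(des), n_iter = 2500, burn_in = 500,
                 seed = 7)
  preds <- cbind(fg$fitted, fe$fitted,
                 as.numeric(sim$X %*% fb$posterior$beta) + fb$posterior$genetic_values,
                 as.numeric(sim$X %*% fr$posterior$beta) + fr$posterior$genetic_values)
  rho <- cor(preds, method = "spearman")
  expect_true(all(rho[upper.tri(rho)] >= 0.95))
})
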