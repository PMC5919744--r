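test_that("GBLUP matches a direct mixed-model-equation solve on a toy", {
  set.seed(91)
  n <- 6
  Z <- matrix(rnorm(n * 12), n, 12)
  K <- tcrossprod(Z) / 12 + diag(0.05, n)
  y <- rnorm(n)
  vc <- list(sigma2_g = 1.3, sigma2_e = 0.7)
  fit <- fit_gblup(y, K, vc = vc)
  # dense solve of Henderson's equations with known variance ratio
  lambda <- vc$sigma2_e / vc$sigma2_g
  Ki <- solve(K)
  ones <- rep(1, n)
  C <- rbind(cbind(n, t(ones)), cbind(ones, diag(n) + lambda * Ki))
  sol <- unname(solve(C, c(sum(y), y)))
  expect_equal(fit$mu, sol[1], tolerance = 1e-8)
  expect_equal(unname(fit$g), sol[-1], tolerance = 1e-8)
})

test_that("GBLUP interpolates in the noiseless limit", {
  sim <- make_panel(n = 80, mpc = 100, chroms = 2, K = 2, seed = 93)
  K <- kinship(sim$geno)
  y <- setNames(sim$truth$g, geno_ids(sim$geno))   # no noise at all
  fit <- fit_gblup(y, K)
  expect_lt(max(abs(fit$g - (y - fit$mu))), 1e-6)
})

test_that("RRBLUP genetic values equal GBLUP's exactly", {
  # the equivalence theorem: K = W W' / c with the same scaling
  for (s in 1:3) {
    sim <- make_panel(n = 100, mpc = 150, chroms = 2, K = 2, seed = 94 + s)
    y <- mean_phenotype(sim$truth$g, 0.7, geno_ids(sim$geno),
                        seed = 200 + s)
    rr <- fit_rrblup(y, sim$geno)
    p <- colMeans(sim$geno$X) / 2
    W <- sweep(sim$geno$X, 2, 2 * p)
    K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
    gb <- fit_gblup(y, K)
    expect_lt(max(abs(rr$g - gb$g)), 1e-8)
  }
})

test_that("RRBLUP handles orthogonal phenotypes and single markers", {
  sim <- make_panel(n = 60, mpc = 15, chroms = 2, K = 1, F = 0,
                    seed = 97)
  # y orthogonal to the marker space (m < n): effects ~ 0
  W <- scale(sim$geno$X, scale = FALSE)
  set.seed(977)
  yo <- resid(lm(rnorm(60) ~ W))
  rr <- fit_rrblup(yo, sim$geno)
  expect_lt(max(abs(rr$effect)), 1e-3)
  # single marker: closed-form univariate ridge
  x <- sim$geno$X[, 1, drop = FALSE]
  set.seed(98)
  y1 <- drop(x) * 0.6 + rnorm(60, 0, 0.4)
  rr1 <- fit_rrblup(y1, x)
  xc <- drop(x) - mean(drop(x))
  p1 <- mean(drop(x)) / 2
  denom <- 2 * p1 * (1 - p1)
  lam <- rr1$sigma2_e / (rr1$sigma2_g / denom)
  # GLS intercept then ridge beta = x'(y - mu) / (x'x + lambda)
  beta_cf <- sum(xc * (y1 - rr1$mu)) / (sum(xc^2) + lam)
  expect_equal(unname(rr1$effect), beta_cf, tolerance = 1e-6)
})

test_that("BayesB degenerates gracefully and is reproducible", {
  sim <- make_panel(n = 60, mpc = 60, chroms = 2, K = 1, F = 0,
                    seed = 99)
  # all-zero phenotype: all posterior-mean effects essentially zero
  y0 <- rep(0, 60)
  bb0 <- fit_bayesb(y0 + rnorm(60, 0, 1e-8), sim$geno, iters = 600,
                    burnin = 200, seed = 1)
  expect_lt(max(abs(bb0$effect)), 1e-3)
  # two chains with different seeds agree on genetic values
  set.seed(100)
  q <- sample(ncol(sim$geno$X), 3)
  y <- drop(sim$geno$X[, q] %*% c(1, -0.8, 0.6))
  y <- y + rnorm(60, 0, sd(y) * 0.5)
  b1 <- fit_bayesb(y, sim$geno, iters = 4000, burnin = 1000, seed = 2)
  b2 <- fit_bayesb(y, sim$geno, iters = 4000, burnin = 1000, seed = 3)
  expect_gt(cor(b1$g, b2$g), 0.99)
  # identical seed: identical draws
  b3 <- fit_bayesb(y, sim$geno, iters = 1000, burnin = 200, seed = 2)
  b4 <- fit_bayesb(y, sim$geno, iters = 1000, burnin = 200, seed = 2)
  expect_identical(b3$effect, b4$effect)
  expect_error(fit_bayesb(y, sim$geno, iters = 100, burnin = 100),
               "exceed")
})

test_that("cross-validation is deterministic and null traits predict nothing", {
  sim <- make_panel(n = 100, mpc = 150, chroms = 2, K = 2, seed = 101)
  y0 <- mean_phenotype(sim$truth$g, 0, geno_ids(sim$geno), seed = 102)
  cv0 <- cross_validate(y0, sim$geno, "gblup", folds = 5, reps = 3,
                        seed = 103)
  expect_lt(abs(cv0$ability), 0.15)
  cv0b <- cross_validate(y0, sim$geno, "gblup", folds = 5, reps = 3,
                         seed = 103)
  expect_identical(cv0$per_fold, cv0b$per_fold)
  expect_equal(nrow(cv0$per_fold), 15)
  # folds partition individuals disjointly: per rep each individual
  # held out exactly once, so fold sizes sum to n
  expect_error(cross_validate(y0[1:3], model = "gblup",
                              K = kinship(sim$geno)[1:3, 1:3],
                              folds = 5), "folds")
})

test_that("effect ranking agrees with association order when they coincide", {
  sim <- make_panel(n = 80, mpc = 60, chroms = 2, K = 1, F = 0,
                    seed = 105)
  m <- ncol(sim$geno$X)
  assoc <- data.frame(marker = colnames(sim$geno$X),
                      p = seq(1e-6, 0.9, length.out = m),
                      significant = c(rep(TRUE, 4), rep(FALSE, m - 4)))
  eff <- structure(list(
    effect = setNames(seq(2, 0.01, length.out = m),
                      colnames(sim$geno$X)),
    mu = 0, model = "rrblup"), class = "marker_effects")
  rk <- rank_effects(eff, assoc)
  expect_equal(rk$ranks$rank, 1:4)
  expect_equal(rk$overlap_top_k, 4)
  # disjoint marker sets error
  eff2 <- eff
  names(eff2$effect) <- paste0("zz", seq_len(m))
  expect_error(rank_effects(eff2, assoc), "disjoint")
})

test_that("planted QTL tops both RRBLUP and BayesB effect rankings", {
  tops <- vapply(1:5, function(s) {
    sim <- make_panel(n = 120, mpc = 150, chroms = 2, K = 1, F = 0,
                      ld = 0.5, h2 = 1, n_qtl = 1, seed = 110 + s)
    q <- sim$truth$qtl_index
    g <- sim$truth$g / sd(sim$truth$g) * sqrt(0.4)
    y <- setNames(g + rnorm(120, 0, sqrt(0.6)), geno_ids(sim$geno))
    rr <- fit_rrblup(y, sim$geno)
    bb <- fit_bayesb(y, sim$geno, iters = 1500, burnin = 500,
                     seed = 120 + s)
    rr_top <- which.max(abs(rr$effect))
    bb_top <- which.max(abs(bb$effect))
    (abs(rr_top - q) <= 1) && (abs(bb_top - q) <= 1)
  }, logical(1))
  expect_gte(mean(tops), 0.8)
})

test_that("marker subsets saturate to the full-panel prediction ability", {
  sim <- make_panel(n = 100, mpc = 150, chroms = 2, K = 3, F = 0.2,
                    h2 = 0.9, n_qtl = 10, seed = 131)
  y <- mean_phenotype(sim$truth$g, 0.9, geno_ids(sim$geno), seed = 132)
  m <- ncol(sim$geno$X)
  curve <- marker_subset_curve(y, sim$geno, sizes = c(25, 100, m),
                               runs = 8, folds = 5, reps = 1,
                               seed = 133)
  full <- cross_validate(y, sim$geno, "gblup", folds = 5, reps = 3,
                         seed = 134)$ability
  # size = m equals the full-data ability within Monte-Carlo error
  expect_lt(abs(curve$ability[curve$size == m] - full),
            4 * curve$se[curve$size == m] + 0.05)
  # structured panel: 100 markers already give > 50% of full ability
  expect_gt(curve$ability[curve$size == 100], 0.5 * full)
  expect_error(marker_subset_curve(y, sim$geno, sizes = 10 * m),
               "exceeds")
})

test_that("structure correction lowers ability only for structured traits", {
  sim <- make_panel(n = 120, mpc = 300, chroms = 3, K = 2, F = 0.3,
                    ld = 0, seed = 141)
  lab <- sim$truth$cluster_labels
  K <- kinship(sim$geno)
  Kc <- pc_adjusted_kinship(sim$geno, n_pcs = 2)
  # cluster-driven trait: correction removes the predictive signal
  set.seed(142)
  yc <- setNames(ifelse(lab == 1, 1, -1) + rnorm(120, 0, 0.7),
                 geno_ids(sim$geno))
  ab_std <- cross_validate(yc, model = "gblup", K = K, folds = 5,
                           reps = 3, seed = 143)$ability
  ab_cor <- cross_validate(yc, model = "gblup", K = Kc, folds = 5,
                           reps = 3, seed = 143)$ability
  expect_gt(ab_std - ab_cor, 0.1)
})
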