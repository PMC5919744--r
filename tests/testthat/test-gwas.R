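test_that("VanRaden kinship matches the direct formula", {
  X <- rbind(c(0, 1, 2, 1), c(2, 1, 0, 0), c(1, 1, 1, 2))
  K <- kinship(X, ridge = 0)
  p <- colMeans(X) / 2
  W <- sweep(X, 2, 2 * p)
  brute <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  expect_equal(K, brute, tolerance = 1e-12, ignore_attr = TRUE)
  # centering: row means of K are ~ 0
  expect_lt(max(abs(rowMeans(brute))), 1e-12)
  # identical individuals: off-diagonal equals diagonal
  X2 <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  K2 <- kinship(X2, ridge = 0)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  expect_error(kinship(matrix(2, 4, 3)), "monomorphic")
})

test_that("EMMAX with identity kinship reproduces OLS", {
  sim <- make_panel(n = 80, mpc = 60, chroms = 2, K = 1, F = 0,
                    ld = 0, seed = 61)
  y <- mean_phenotype(sim$truth$g, 0.5, geno_ids(sim$geno), seed = 62)
  K <- diag(nrow(sim$geno$X))
  as <- emmax_scan(y, sim$geno, K, test = "f")
  ols <- apply(sim$geno$X, 2, function(x)
    summary(lm(y ~ x))$coefficients[2, 4])
  expect_equal(as$p, unname(ols), tolerance = 1e-10)
})

test_that("EMMAX agrees with exact per-marker REML on structured data", {
  sim <- make_panel(n = 120, mpc = 100, chroms = 2, K = 3, F = 0.2,
                    seed = 63)
  y <- mean_phenotype(sim$truth$g, 0.8, geno_ids(sim$geno), seed = 64)
  K <- kinship(sim$geno)
  as <- emmax_scan(y, sim$geno, K)
  exact_p <- vapply(1:50, function(j) {
    X0 <- cbind(1, sim$geno$X[, j])
    fit <- curdpred:::reml_kinship(y, K = K, X = X0)
    w <- 1 / (fit$eig$values + fit$delta)
    tX <- crossprod(fit$eig$vectors, X0)
    Vb <- solve(crossprod(tX, tX * w))[2, 2] * fit$sigma2_g
    pchisq(fit$beta[2]^2 / Vb, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(cor(exact_p, as$p[1:50], method = "spearman"), 0.99)
})

test_that("permuted phenotypes are calibrated under a structured kinship", {
  sim <- make_panel(n = 150, mpc = 500, chroms = 3, K = 3, F = 0.2,
                    ld = 0, seed = 65)
  y <- mean_phenotype(sim$truth$g, 0.6, geno_ids(sim$geno), seed = 66)
  yp <- setNames(sample(y), names(y))
  as <- emmax_scan(yp, sim$geno)
  expect_gt(ks.test(as$p, "punif")$p.value, 0.01)
  expect_gt(attr(as, "lambda"), 0.9)
  expect_lt(attr(as, "lambda"), 1.1)
  expect_error(emmax_scan(setNames(rep(1, 150), names(y)), sim$geno),
               "constant")
})

test_that("the genomic inflation factor matches its definition", {
  expect_equal(inflation_factor(rep(0.5, 100)), 1, tolerance = 1e-12)
  set.seed(67)
  # chi-square statistics inflated 2x
  stats <- rchisq(1e5, 1) * 2
  p <- pchisq(stats, 1, lower.tail = FALSE)
  expect_equal(inflation_factor(p), 2, tolerance = 0.05)
  # uniform null
  expect_lt(abs(inflation_factor(runif(1e5)) - 1), 0.02)
  expect_error(inflation_factor(c(0.5, -0.1, rep(0.5, 10))), "0, 1")
  expect_error(inflation_factor(rep(0.5, 5)), ">= 10")
})

test_that("Benjamini-Hochberg step-up flags match the hand example", {
  p <- c(0.001, 0.01, 0.02, 0.5)
  expect_equal(bh_fdr(p, Q = 0.2), c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10), Q = 0.2)))
  m <- 20
  expect_true(all(bh_fdr(runif(m, 0, 0.2 / m), Q = 0.2)))
  # agrees with p.adjust step-up on random inputs
  set.seed(68)
  for (i in 1:20) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p, 0.2), p.adjust(p, "BH") <= 0.2)
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(0.5, Q = 1.2), "Q")
})

test_that("variance explained follows the adjusted-R2 and rho formulas", {
  expect_equal(adjust_r2(0.2, 1, 174), 0.2 - (1 / 172) * 0.8,
               tolerance = 1e-12)
  expect_error(adjust_r2(0.2, 200, 174), "z")
  rho <- genotypic_variance_explained(0.191, 0.56)
  expect_equal(as.numeric(rho), 0.191 / 0.56, tolerance = 1e-12)
  expect_false(attr(rho, "exceeds_one"))
  rho2 <- genotypic_variance_explained(0.5, 0.3)
  expect_true(attr(rho2, "exceeds_one"))
  expect_error(genotypic_variance_explained(0.2, 0), "h2")
  # data route: R2 = 0 reports R2_adj = 0
  sim <- make_panel(n = 60, mpc = 40, chroms = 2, K = 1, F = 0,
                    seed = 69)
  y <- setNames(rep(c(1, 2), 30), geno_ids(sim$geno))
  ve <- variance_explained(y, sim$geno, markers = 1:2, h2 = 0.5)
  expect_gte(ve$r2_adj, 0)
  expect_equal(ve$z, 2)
})

test_that("MLMM selects planted cofactors and nothing under the null", {
  # dense polygene (every marker a tiny effect): no single cofactor
  # should survive selection
  sim <- make_panel(n = 120, mpc = 100, chroms = 2, K = 3, F = 0.2,
                    seed = 71, n_qtl = 200)
  K <- kinship(sim$geno)
  y0 <- mean_phenotype(sim$truth$g, 0.6, geno_ids(sim$geno), seed = 72)
  ml0 <- mlmm_scan(y0, sim$geno, K, max_steps = 5)
  expect_length(ml0$cofactors, 0)
  # two strong unlinked QTL on a thinned marker set: the selected pair
  # matches the exhaustive two-cofactor REML-likelihood optimum
  cand <- sort(unique(c(30, 150, seq(1, 200, by = 4))))
  gsub <- sim$geno[, cand]
  Ks <- kinship(gsub)
  qpos <- match(c(30, 150), cand)
  set.seed(73)
  yq <- drop(gsub$X[, qpos] %*% c(1, -1))
  yq <- setNames(yq + rnorm(120, 0, sd(yq) * 0.4), geno_ids(gsub))
  ml <- mlmm_scan(yq, gsub, Ks, max_steps = 6)
  expect_length(ml$cofactors, 2)
  eig <- curdpred:::reml_eigen(Ks)
  mm <- ncol(gsub$X)
  best <- NULL; bestll <- -Inf
  for (i in seq_len(mm)) for (j in seq_len(i - 1)) {
    X0 <- cbind(1, gsub$X[, c(i, j)])
    if (qr(X0)$rank < 3) next
    ll <- curdpred:::reml_kinship(yq, X = X0, eig = eig)$loglik_ml
    if (ll > bestll) { bestll <- ll; best <- c(j, i) }
  }
  expect_setequal(match(ml$cofactors, colnames(gsub$X)), best)
  # final cofactors always a subset of forward-step selections
  expect_true(all(ml$cofactors %in% ml$forward_cofactors))
})

test_that("single planted QTL is found at the first forward step", {
  hits <- vapply(1:10, function(s) {
    sim <- make_panel(n = 150, mpc = 150, chroms = 2, K = 2, F = 0.2,
                      h2 = 1, n_qtl = 1, seed = 80 + s)
    q <- sim$truth$qtl_index
    g <- sim$truth$g / sd(sim$truth$g) * sqrt(0.3)
    y <- setNames(g + rnorm(150, 0, sqrt(0.7)), geno_ids(sim$geno))
    ml <- mlmm_scan(y, sim$geno, max_steps = 2)
    first <- ml$steps$cofactor[2]
    abs(match(first, colnames(sim$geno$X)) - q) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
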