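# One-component REML on a kinship matrix via eigendecomposition (the
# EMMA trick): model y = X b + u + e, u ~ N(0, sigma2_g K),
# e ~ N(0, sigma2_e I).  Profiling over delta = sigma2_e / sigma2_g
# reduces REML to a 1-D optimization on the rotated data.

reml_eigen <- function(K) {
  ek <- eigen(K, symmetric = TRUE)
  ek$values <- pmax(ek$values, 1e-10)
  ek
}

# REML log-likelihood (up to a constant) at a given log(delta)
reml_profile <- function(log_delta, d, ty, tX) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(tX, tX * w)
  XtWy <- crossprod(tX, ty * w)
  beta <- solve(XtWX, XtWy)
  r <- ty - tX %*% beta
  rss <- sum(w * r^2)
  n <- length(ty); p <- ncol(tX)
  s2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(d + delta)) +
                  determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  # ML log-likelihood at the same (delta, beta): comparable across
  # fixed-effect sets, used for model selection
  ll_ml <- -0.5 * (n * log(2 * pi * rss / n) + sum(log(d + delta)) + n)
  list(ll = as.numeric(ll), ll_ml = as.numeric(ll_ml), sigma2_g = s2,
       delta = delta, beta = beta, rss = rss)
}

# Fit the null mixed model.  X defaults to an intercept.  eig may be a
# precomputed eigen(K).
reml_kinship <- function(y, K = NULL, X = NULL, eig = NULL) {
  n <- length(y)
  if (sd(y) == 0) stop("phenotype is constant")
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(eig)) eig <- reml_eigen(K)
  d <- eig$values
  U <- eig$vectors
  ty <- drop(crossprod(U, y))
  tX <- crossprod(U, X)
  grid <- seq(-18, 18, length.out = 73)
  lls <- vapply(grid, function(ld) reml_profile(ld, d, ty, tX)$ll,
                numeric(1))
  best <- grid[which.max(lls)]
  opt <- optimize(function(ld) reml_profile(ld, d, ty, tX)$ll,
                  interval = c(best - 1, best + 1), maximum = TRUE,
                  tol = 1e-8)
  fit <- reml_profile(opt$maximum, d, ty, tX)
  list(sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_g * fit$delta,
       delta = fit$delta, beta = drop(fit$beta), loglik = fit$ll,
       loglik_ml = fit$ll_ml, eig = eig, ty = ty, tX = tX)
}
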