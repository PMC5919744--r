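#' Realized relationship (kinship) matrix
#'
#' VanRaden's first method: dosages centered by twice the allele
#' frequency, `K = W W' / (2 sum p (1 - p))`, ridged by 1e-6 on the
#' diagonal so K stays positive definite.
#'
#' @param g a complete [geno_matrix()], or a plain dosage matrix.
#' @param ridge diagonal ridge (default 1e-6).
#' @return Symmetric positive-definite n x n matrix with a
#'   `method = "vanraden"` attribute.
#' @export
kinship <- function(g, ridge = 1e-6) {
  X <- if (inherits(g, "geno_matrix")) {
    check_geno(g, complete = TRUE)
    g$X
  } else as.matrix(g)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; kinship undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  K <- K + diag(ridge, nrow(K))
  attr(K, "method") <- "vanraden"
  K
}

#' Single-marker mixed-model association scan (EMMAX)
#'
#' Fits the null model y = X b + u + e with u ~ N(0, sigma2_a K) by
#' REML through the eigendecomposition of K, then fixes the variance
#' components and tests each marker by generalized least squares on the
#' rotated data (Wald chi-squared with 1 df; an F test with residual
#' df is available via `test`).  This is the approximation that makes
#' genome scans on structured panels fast: the variance components are
#' estimated once, not per marker.
#'
#' @param y named numeric vector of per-genotype phenotype summaries
#'   (BLUEs/adjusted means), aligned with `g`'s individuals.
#' @param g a complete [geno_matrix()].
#' @param K kinship matrix (default [kinship()] of `g`).
#' @param covariates optional n x c matrix of fixed covariates
#'   (an intercept is always included).
#' @param test `"wald"` (chi-squared, 1 df) or `"f"`.
#' @return An `assoc_table` data.frame: marker, chrom, pos, maf, beta,
#'   se, p; attributes `sigma2_a`, `sigma2_e`, `lambda` (genomic
#'   inflation of this scan).
#' @export
emmax_scan <- function(y, g, K = NULL, covariates = NULL,
                       test = c("wald", "f")) {
  test <- match.arg(test)
  check_geno(g, complete = TRUE)
  y <- align_phenotype(y, g)
  if (is.null(K)) K <- kinship(g)
  if (nrow(K) != length(y)) stop("K not conformable with y")
  C <- cbind(intercept = rep(1, length(y)), covariates)
  null <- reml_kinship(y, K = K, X = C)
  res <- gls_scan(null, g$X, C)
  maf <- compute_maf(g)
  out <- data.frame(marker = colnames(g$X), chrom = g$map$chrom,
                    pos = g$map$pos, maf = maf, beta = res$beta,
                    se = res$se, p = res$p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (test == "f") {
    # F with per-marker residual variance and residual df; with
    # K = identity this reduces exactly to the single-marker OLS test
    dfres <- length(y) - ncol(C) - 1
    ssm <- res$xMy^2 / res$xMx
    fstat <- dfres * ssm / (res$yMy - ssm)
    out$p <- pf(fstat, 1, dfres, lower.tail = FALSE)
  }
  attr(out, "sigma2_a") <- null$sigma2_g
  attr(out, "sigma2_e") <- null$sigma2_e
  attr(out, "lambda") <- inflation_factor(out$p[!is.na(out$p)])
  class(out) <- c("assoc_table", "data.frame")
  out
}

# vectorized GLS marker tests given a fitted null model
gls_scan <- function(null, X, C) {
  U <- null$eig$vectors
  w <- 1 / (null$eig$values + null$delta)
  ty <- null$ty
  tC <- crossprod(U, C)
  tXm <- crossprod(U, X)
  CtWC <- crossprod(tC, tC * w)
  CtWy <- crossprod(tC, ty * w)
  ry <- ty * w - (tC * w) %*% solve(CtWC, CtWy)   # M y with M = W - WC(C'WC)^-1 C'W
  xMy <- drop(crossprod(tXm, ry))
  A <- crossprod(tC, tXm * w)                     # C' W X
  B <- solve(CtWC, A)
  xMx <- colSums(tXm^2 * w) - colSums(A * B)
  ok <- xMx > 1e-10
  beta <- se <- p <- rep(NA_real_, ncol(X))
  beta[ok] <- xMy[ok] / xMx[ok]
  se[ok] <- sqrt(null$sigma2_g / xMx[ok])
  chi <- (beta / se)^2
  p[ok] <- pchisq(chi[ok], df = 1, lower.tail = FALSE)
  p[ok] <- pmax(p[ok], .Machine$double.xmin)      # keep p in (0, 1]
  yMy <- sum(ty * ry)
  xMy[!ok] <- NA_real_
  xMx[!ok] <- NA_real_
  list(beta = beta, se = se, p = p, xMy = xMy, xMx = xMx, yMy = yMy)
}

align_phenotype <- function(y, g) {
  ids <- rownames(g$X)
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y)))
      stop("phenotype is missing individuals: ",
           paste(head(setdiff(ids, names(y)), 3), collapse = ", "))
    y <- y[ids]
  } else if (length(y) != nrow(g$X)) {
    stop("unnamed phenotype must match the number of individuals")
  }
  as.numeric(y)
}

#' Multi-locus mixed-model scan (forward-backward cofactor selection)
#'
#' Extends the single-marker mixed model by stepwise inclusion of the
#' currently most significant marker as a fixed cofactor, with variance
#' components re-estimated at every step.  After `max_steps` forward
#' steps the model minimizing the selection criterion (extended BIC by
#' default, with a marker-count penalty; `"mbonf"` keeps the largest
#' model whose cofactors all pass a Bonferroni threshold) is retained,
#' and a backward pass drops cofactors that lost significance.
#'
#' @inheritParams emmax_scan
#' @param max_steps maximum number of forward steps.
#' @param criterion `"ebic"` or `"mbonf"`.
#' @param alpha significance level for the Bonferroni-style backward
#'   pruning threshold `alpha / m`.
#' @return An `mlmm_path` list: `steps` (per-step cofactor, variance
#'   components, min p, criterion value), `cofactors` (final selected
#'   marker names), `final_scan` (assoc_table of the final model),
#'   `criterion`.
#' @export
mlmm_scan <- function(y, g, K = NULL, max_steps = 10,
                      criterion = c("ebic", "mbonf"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  check_geno(g, complete = TRUE)
  y <- align_phenotype(y, g)
  if (is.null(K)) K <- kinship(g)
  eig <- reml_eigen(K)
  m <- ncol(g$X)
  n <- length(y)
  cof <- integer(0)
  steps <- list()
  scans <- list()
  for (s in 0:max_steps) {
    C <- cbind(intercept = rep(1, n),
               if (length(cof)) g$X[, cof, drop = FALSE])
    # drop collinear cofactors
    qrC <- qr(C)
    if (qrC$rank < ncol(C)) {
      keep <- qrC$pivot[seq_len(qrC$rank)]
      dropped <- setdiff(seq_len(ncol(C)), keep)
      warning("dropping collinear cofactor(s): ",
              paste(colnames(C)[dropped], collapse = ", "))
      cof <- cof[keep[keep > 1] - 1]
      C <- C[, keep, drop = FALSE]
    }
    null <- reml_kinship(y, X = C, eig = eig)
    res <- gls_scan(null, g$X, C)
    res$p[cof] <- NA
    scans[[s + 1]] <- res
    k <- length(cof)
    ebic <- -2 * null$loglik_ml + k * (log(n) + 2 * log(m))
    minp <- suppressWarnings(min(res$p, na.rm = TRUE))
    steps[[s + 1]] <- data.frame(
      step = s, n_cofactors = k,
      cofactor = if (k) colnames(g$X)[cof[k]] else NA_character_,
      sigma2_a = null$sigma2_g, sigma2_e = null$sigma2_e,
      min_p = if (is.finite(minp)) minp else NA_real_,
      ebic = ebic, stringsAsFactors = FALSE)
    if (s == max_steps || !is.finite(minp)) break
    # pseudo-heritability exhausted: stop adding cofactors
    if (null$sigma2_g / (null$sigma2_g + null$sigma2_e) < 1e-3 && s > 0)
      break
    cof <- c(cof, which.min(res$p))
  }
  path <- do.call(rbind, steps)
  all_cof <- path$cofactor[!is.na(path$cofactor)]
  sel <- select_mlmm_model(path, scans, g, y, eig, criterion, alpha, m)
  cof <- sel$cof
  # backward pass: drop cofactors whose conditional p exceeds alpha/m
  repeat {
    if (!length(cof)) break
    pc <- cofactor_pvalues(y, g, cof, eig)
    worst <- which.max(pc)
    if (pc[worst] <= alpha / m) break
    cof <- cof[-worst]
  }
  C <- cbind(intercept = rep(1, n),
             if (length(cof)) g$X[, cof, drop = FALSE])
  null <- reml_kinship(y, X = C, eig = eig)
  res <- gls_scan(null, g$X, C)
  maf <- compute_maf(g)
  final <- data.frame(marker = colnames(g$X), chrom = g$map$chrom,
                      pos = g$map$pos, maf = maf, beta = res$beta,
                      se = res$se, p = res$p,
                      cofactor = seq_len(m) %in% cof,
                      stringsAsFactors = FALSE)
  attr(final, "sigma2_a") <- null$sigma2_g
  attr(final, "sigma2_e") <- null$sigma2_e
  attr(final, "lambda") <- inflation_factor(final$p[!is.na(final$p)])
  class(final) <- c("assoc_table", "data.frame")
  structure(list(steps = path, cofactors = colnames(g$X)[cof],
                 forward_cofactors = all_cof,
                 final_scan = final, criterion = criterion),
            class = "mlmm_path")
}

select_mlmm_model <- function(path, scans, g, y, eig, criterion,
                              alpha, m) {
  cof_at <- function(step) {
    nm <- path$cofactor[seq_len(step + 1)]
    match(nm[!is.na(nm)], colnames(g$X))
  }
  if (criterion == "ebic") {
    best <- path$step[which.min(path$ebic)]
    return(list(cof = cof_at(best)))
  }
  # mbonf: largest model whose cofactors all pass alpha / m
  for (s in rev(path$step)) {
    cof <- cof_at(s)
    if (!length(cof)) return(list(cof = integer(0)))
    pc <- cofactor_pvalues(y, g, cof, eig)
    if (all(pc <= alpha / m)) return(list(cof = cof))
  }
  list(cof = integer(0))
}

# conditional p-value of each cofactor given the others (VCs re-estimated)
cofactor_pvalues <- function(y, g, cof, eig) {
  vapply(seq_along(cof), function(i) {
    others <- cof[-i]
    C <- cbind(intercept = rep(1, length(y)),
               if (length(others)) g$X[, others, drop = FALSE])
    null <- reml_kinship(y, X = C, eig = eig)
    res <- gls_scan(null, g$X[, cof[i], drop = FALSE], C)
    res$p
  }, numeric(1))
}

#' @export
print.mlmm_path <- function(x, ...) {
  cat(sprintf("mlmm_path (%s): %d forward step(s), %d cofactor(s) retained\n",
              x$criterion, nrow(x$steps) - 1, length(x$cofactors)))
  if (length(x$cofactors))
    cat("cofactors:", paste(x$cofactors, collapse = ", "), "\n")
  invisible(x)
}

#' Genomic inflation factor
#'
#' lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1); the ratio of the
#' observed to the expected median association test statistic.  Values
#' near 1 indicate that population structure is properly accounted for.
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return Scalar lambda.
#' @export
inflation_factor <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 10) stop("need >= 10 p-values")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must be in (0, 1]")
  median(qchisq(pvalues, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Flags all p-values at or below p_(k), where k is the largest rank
#' with p_(k) <= (k / m) Q.
#'
#' @param pvalues vector of p-values.
#' @param Q target false discovery rate (default 0.2).
#' @return Logical vector of flags, same order as `pvalues`.
#' @export
bh_fdr <- function(pvalues, Q = 0.2) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (Q <= 0 || Q >= 1) stop("Q must be in (0, 1)")
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  ok <- which(ps <= (seq_len(m) / m) * Q)
  flags <- rep(FALSE, m)
  if (length(ok)) flags[ord[seq_len(max(ok))]] <- TRUE
  flags[is.na(pvalues)] <- FALSE
  flags
}

#' Adjusted R-squared for a fixed number of predictors
#'
#' `R2_adj = R2 - z (1 - R2) / (N - z - 1)`.
#'
#' @param r2 coefficient of determination.
#' @param z number of predictors (significant SNPs).
#' @param n number of observations.
#' @return Adjusted R-squared (may be negative).
#' @export
adjust_r2 <- function(r2, z, n) {
  if (z >= n - 1) stop("z must be < n - 1")
  r2 - z * (1 - r2) / (n - z - 1)
}

#' Proportion of genotypic variance explained
#'
#' The adjusted phenotypic variance explained by significant SNPs,
#' rescaled by the trait's broad-sense heritability:
#' `rho = R2_adj / H2`.  Values above 1 can occur when R2_adj
#' overshoots the genetic signal and are reported with a flag rather
#' than truncated.
#'
#' @param r2_adj adjusted R-squared of the multi-SNP fit (proportion,
#'   not percent).
#' @param h2 broad-sense heritability in (0, 1].
#' @return `rho` with attribute `exceeds_one`.
#' @export
genotypic_variance_explained <- function(r2_adj, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  rho <- r2_adj / h2
  attr(rho, "exceeds_one") <- rho > 1
  rho
}

#' Variance explained by significant SNPs
#'
#' Multiple linear regression of the phenotype on the given SNP
#' dosages; reports R2, the predictor-count-adjusted R2 (negative
#' values reported as 0) and the proportion of genotypic variance
#' `rho = R2_adj / H2`.
#'
#' @param y named phenotype vector.
#' @param g a complete [geno_matrix()].
#' @param markers marker names or column indices of the significant
#'   SNPs.
#' @param h2 broad-sense heritability of the trait.
#' @return list with `r2`, `r2_adj`, `rho` (with `exceeds_one`
#'   attribute), `z`, `n`.
#' @export
variance_explained <- function(y, g, markers, h2) {
  check_geno(g, complete = TRUE)
  y <- align_phenotype(y, g)
  if (is.character(markers)) markers <- match(markers, colnames(g$X))
  if (anyNA(markers)) stop("unknown marker name(s)")
  Xs <- g$X[, markers, drop = FALSE]
  z <- ncol(Xs)
  n <- length(y)
  if (z >= n - 1) stop("more predictors than observations allow")
  r2 <- summary(lm(y ~ Xs))$r.squared
  r2a <- max(0, adjust_r2(r2, z, n))
  list(r2 = r2, r2_adj = r2a,
       rho = genotypic_variance_explained(r2a, h2), z = z, n = n)
}
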