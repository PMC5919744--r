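#' Principal components of a genotype matrix
#'
#' PCA on centered, frequency-scaled dosages (each marker scaled by
#' sqrt(2 p (1 - p))).  Missing calls are mean-filled for the
#' decomposition only.
#'
#' @param g a [geno_matrix()].
#' @param n_pcs number of components to retain, or `"auto"` to keep the
#'   smallest number capturing 90% of the variance.
#' @return A list with `scores` (n x n_pcs), `rotation` (m x n_pcs),
#'   `var_explained` (per retained PC), and `n_pcs`.
#' @export
snp_pca <- function(g, n_pcs = "auto") {
  check_geno(g)
  Z <- scale_dosages(g$X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (identical(n_pcs, "auto"))
    n_pcs <- max(1, which(cumsum(ve) >= 0.9)[1])
  n_pcs <- min(n_pcs, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
       var_explained = ve[seq_len(n_pcs)], n_pcs = n_pcs)
}

# center by 2p and scale by sqrt(2p(1-p)); mean-fill missing
scale_dosages <- function(X) {
  p <- colMeans(X, na.rm = TRUE) / 2
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  Z <- sweep(X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
}

#' Infer genetic clusters by k-means on principal components
#'
#' The DAPC-style find-clusters procedure: k-means (20 restarts) on
#' retained PC scores for each candidate K, scored by a BIC computed
#' from the within-cluster sum of squares under a spherical Gaussian
#' likelihood, `BIC(K) = n log(WSS/n) + K log(n)`.  K is chosen at the
#' minimum BIC.
#'
#' @param g a [geno_matrix()] (complete or mean-filled for PCA).
#' @param k_range integer vector of candidate K values.
#' @param n_pcs PCs to retain (`"auto"` = 90% variance).
#' @param seed integer RNG seed (k-means restarts).
#' @return A `cluster_solution` list: `K`, `labels` (1..K per
#'   individual), `bic` (named by K), `scores`, `n_pcs`.
#' @export
find_clusters <- function(g, k_range = 1:10, n_pcs = "auto", seed = 1) {
  check_geno(g)
  if (max(k_range) >= nrow(g$X))
    stop("k_range upper bound must be < number of individuals")
  pca <- snp_pca(g, n_pcs)
  S <- pca$scores
  set.seed(seed)
  n <- nrow(S)
  bic <- setNames(numeric(length(k_range)), k_range)
  labs <- vector("list", length(k_range))
  for (idx in seq_along(k_range)) {
    K <- k_range[idx]
    if (K == 1) {
      wss <- sum(scale(S, scale = FALSE)^2)
      labs[[idx]] <- rep(1L, n)
    } else {
      km <- kmeans(S, centers = K, nstart = 20, iter.max = 100)
      wss <- km$tot.withinss
      labs[[idx]] <- km$cluster
    }
    bic[idx] <- n * log(wss / n) + K * log(n)
  }
  best <- which.min(bic)
  structure(list(K = k_range[best], labels = labs[[best]], bic = bic,
                 scores = S, n_pcs = pca$n_pcs),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: K = %d (BIC-selected from K = %s), %d PCs\n",
              x$K, paste(range(as.integer(names(x$bic))), collapse = ".."),
              x$n_pcs))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Discriminant-analysis-of-PCs marker loadings
#'
#' Linear discriminant analysis on retained PC scores against cluster
#' labels; discriminant axes are back-projected to marker space through
#' the PC rotation and each function's squared loadings are normalized
#' to sum to 1.  High-loading markers are those driving cluster
#' differentiation.
#'
#' @param g a [geno_matrix()].
#' @param labels integer cluster labels (1..K).
#' @param n_pcs PCs to retain.
#' @param n_da number of discriminant functions (< K).
#' @return An m x n_da matrix of normalized marker loadings.
#' @export
dapc_loadings <- function(g, labels, n_pcs = "auto", n_da = NULL) {
  check_geno(g)
  labels <- as.integer(labels)
  K <- length(unique(labels))
  if (K < 2) stop("need >= 2 clusters for discriminant analysis")
  if (is.null(n_da)) n_da <- K - 1
  if (n_da >= K) stop("n_da must be < number of clusters")
  pca <- snp_pca(g, n_pcs)
  ld <- MASS::lda(pca$scores, grouping = factor(labels))
  W <- ld$scaling[, seq_len(min(n_da, ncol(ld$scaling))), drop = FALSE]
  L <- pca$rotation %*% W
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  colnames(L) <- paste0("DA", seq_len(ncol(L)))
  rownames(L) <- colnames(g$X)
  L
}

#' Structure-corrected kinship (PC-residual surrogate)
#'
#' A PC-Relate-inspired surrogate, declared as such: each marker's
#' dosages are regressed on the top `n_pcs` PC scores (capturing
#' individual-specific ancestry), and the realized relationship matrix
#' is rebuilt from the residuals with the usual VanRaden scaling.  The
#' full PC-Relate estimator is not reimplemented.
#'
#' With `n_pcs = "auto"` only principal components whose eigenvalue
#' exceeds the Marchenko-Pastur upper edge (the largest eigenvalue
#' expected from an unstructured panel of the same dimensions, with a
#' 5% margin) are regressed out, so a panmictic panel is left
#' essentially untouched.
#'
#' @param g a complete [geno_matrix()].
#' @param n_pcs number of PCs to regress out, or `"auto"`.
#' @return Symmetric n x n corrected kinship matrix (ridge 1e-6).
#' @export
pc_adjusted_kinship <- function(g, n_pcs = "auto") {
  check_geno(g, complete = TRUE)
  n <- nrow(g$X)
  m <- ncol(g$X)
  if (identical(n_pcs, "auto")) {
    Z <- scale_dosages(g$X)
    ev <- prcomp(Z, center = FALSE)$sdev^2         # eigenvalues of cov(Z)
    edge <- (1 + sqrt(n / m))^2 * m / (n - 1)      # MP upper edge, same scale
    n_pcs <- sum(ev > 1.05 * edge)
    if (n_pcs == 0) return(kinship(g))
  }
  if (n_pcs >= n) stop("n_pcs must be < number of individuals")
  pca <- snp_pca(g, n_pcs)
  B <- cbind(1, pca$scores)
  # residuals of each marker on [1, PCs] in one shot
  H <- B %*% solve(crossprod(B), t(B))
  R <- g$X - H %*% g$X
  p <- colMeans(g$X) / 2
  denom <- 2 * sum(p * (1 - p))
  Kc <- tcrossprod(R) / denom
  Kc + diag(1e-6, n)
}

#' Phenotypic variance explained by leading principal components
#'
#' Univariate regression of a trait on each of the first `n_pcs` PC
#' scores; reports R-squared per component.
#'
#' @param trait_means named numeric vector of per-genotype trait values.
#' @param pc_scores matrix of PC scores with rownames matching the
#'   trait names (extra individuals are dropped).
#' @param n_pcs number of leading components to report.
#' @return Named numeric vector of R-squared values, one per PC.
#' @export
pc_variance_explained <- function(trait_means, pc_scores, n_pcs = 3) {
  if (!is.null(rownames(pc_scores)) && !is.null(names(trait_means))) {
    shared <- intersect(names(trait_means), rownames(pc_scores))
    if (length(shared) < 3) stop("fewer than 3 shared individuals")
    trait_means <- trait_means[shared]
    pc_scores <- pc_scores[shared, , drop = FALSE]
  }
  if (sd(trait_means) == 0) stop("constant trait; R2 undefined")
  n_pcs <- min(n_pcs, ncol(pc_scores))
  r2 <- vapply(seq_len(n_pcs), function(k)
    summary(lm(trait_means ~ pc_scores[, k]))$r.squared, numeric(1))
  setNames(r2, paste0("PC", seq_len(n_pcs)))
}
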