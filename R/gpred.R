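#' GBLUP: genomic best linear unbiased prediction
#'
#' Model y = 1 mu + g + e with g ~ N(0, sigma2_g K).  Variance
#' components are estimated by REML on the training individuals (via
#' the eigendecomposition of K) unless supplied, and genetic values are
#' predicted for all individuals through the kinship cross-block:
#' g_hat = sigma2_g K[, train] V^-1 (y_train - mu).
#'
#' @param y named phenotype vector for the training individuals (or all
#'   individuals; see `train`).
#' @param K kinship matrix over all individuals (row/col names used for
#'   alignment when available).
#' @param train indices of training individuals within K (default all).
#' @param vc optional list with `sigma2_g` and `sigma2_e` to skip REML.
#' @return list with `g` (predicted genetic values for every individual
#'   in K), `mu`, `sigma2_g`, `sigma2_e`.
#' @export
fit_gblup <- function(y, K, train = NULL, vc = NULL) {
  n <- nrow(K)
  if (is.null(train)) train <- seq_len(n)
  Ktr <- K[train, train, drop = FALSE]
  y <- as.numeric(y)
  if (length(y) != length(train))
    stop("y must have one value per training individual")
  if (is.null(vc)) {
    fit <- reml_kinship(y, K = Ktr)
    sigma2_g <- fit$sigma2_g; sigma2_e <- fit$sigma2_e
  } else {
    sigma2_g <- vc$sigma2_g; sigma2_e <- vc$sigma2_e
  }
  V <- sigma2_g * Ktr + diag(sigma2_e, length(train))
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular mixed-model coefficient matrix: ",
         conditionMessage(e), call. = FALSE))
  one <- rep(1, length(train))
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  gh <- drop(sigma2_g * K[, train, drop = FALSE] %*% (Vi %*% (y - mu)))
  names(gh) <- rownames(K)
  list(g = gh, mu = mu, sigma2_g = sigma2_g, sigma2_e = sigma2_e)
}

#' RRBLUP: ridge-regression BLUP of marker effects
#'
#' Model y = 1 mu + X beta + e with beta ~ N(0, I sigma2_b).  The
#' shrinkage level comes from REML on the equivalent GBLUP model
#' (kinship built from the same centered markers), which makes the
#' fitted genetic values X beta_hat identical to GBLUP's — the
#' classical RRBLUP/GBLUP equivalence.
#'
#' @param y phenotype vector for the training individuals.
#' @param g a complete [geno_matrix()] (or dosage matrix) over all
#'   individuals.
#' @param train training indices (default all).
#' @return A `marker_effects` list: `effect` (named per-marker BLUP),
#'   `mu`, `g` (predicted genetic values for all individuals),
#'   `sigma2_g`, `sigma2_e`.
#' @export
fit_rrblup <- function(y, g, train = NULL) {
  X <- if (inherits(g, "geno_matrix")) {
    check_geno(g, complete = TRUE)
    g$X
  } else as.matrix(g)
  n <- nrow(X)
  if (is.null(train)) train <- seq_len(n)
  keep <- apply(X[train, , drop = FALSE], 2, sd) > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " zero-variance marker column(s)")
  p <- colMeans(X[train, keep, drop = FALSE]) / 2
  denom <- 2 * sum(p * (1 - p))
  W <- sweep(X[, keep, drop = FALSE], 2, 2 * p)
  Wtr <- W[train, , drop = FALSE]
  # no ridge here: the GBLUP equivalence g_hat = W beta_hat is exact
  # only for K = W W' / denom; V = sigma2_g K + sigma2_e I stays PD
  K <- tcrossprod(Wtr) / denom
  fit <- reml_kinship(as.numeric(y), K = K)
  sigma2_g <- fit$sigma2_g; sigma2_e <- fit$sigma2_e
  V <- sigma2_g * K + diag(sigma2_e, length(train))
  Vi <- solve(V)
  one <- rep(1, length(train))
  mu <- drop(crossprod(one, Vi %*% as.numeric(y)) /
               crossprod(one, Vi %*% one))
  alpha <- Vi %*% (as.numeric(y) - mu)
  beta <- drop((sigma2_g / denom) * crossprod(Wtr, alpha))
  eff <- setNames(rep(0, ncol(X)), colnames(X))
  eff[keep] <- beta
  gh <- drop(W %*% beta)
  names(gh) <- rownames(X)
  structure(list(effect = eff, mu = mu, g = gh, sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, model = "rrblup"),
            class = "marker_effects")
}

#' BayesB: Gibbs sampling of sparse marker effects
#'
#' Marker effects follow a mixture of a point mass at zero and a
#' scaled-t slab (normal with a marker-specific variance carrying a
#' scaled inverse chi-squared prior); the mixing proportion pi has a
#' Beta prior, enabling variable selection.  Hyper-parameter defaults
#' follow the usual genomic-prediction heuristic: the slab scale is
#' solved so the prior genetic variance matches `r2_prior` times the
#' phenotypic variance.
#'
#' @param y phenotype vector (training individuals).
#' @param g complete [geno_matrix()] or dosage matrix (all
#'   individuals).
#' @param train training indices (default all).
#' @param iters,burnin,thin Gibbs chain settings.
#' @param df_beta slab degrees of freedom.
#' @param pi0 prior mean of the nonzero proportion pi.
#' @param p0 prior count for the Beta prior on pi.
#' @param r2_prior prior proportion of phenotypic variance attributed
#'   to markers (sets the slab scale).
#' @param seed integer RNG seed (chains are seed-deterministic).
#' @return A `marker_effects` list: posterior-mean `effect`,
#'   `inclusion` (posterior inclusion frequency per marker), `mu`, `g`
#'   (posterior-mean genetic values for all individuals), `sigma2_e`,
#'   `pi`.
#' @export
fit_bayesb <- function(y, g, train = NULL, iters = 5000, burnin = 1000,
                       thin = 5, df_beta = 5, pi0 = 0.5, p0 = 10,
                       r2_prior = 0.5, seed = 1) {
  if (iters <= burnin) stop("iters must exceed burnin")
  X <- if (inherits(g, "geno_matrix")) {
    check_geno(g, complete = TRUE)
    g$X
  } else as.matrix(g)
  n <- nrow(X)
  if (is.null(train)) train <- seq_len(n)
  p <- colMeans(X[train, , drop = FALSE]) / 2
  W <- sweep(X, 2, 2 * p)
  Wtr <- W[train, , drop = FALSE]
  yt <- as.numeric(y)
  vy <- var(yt)
  if (vy == 0) stop("phenotype is constant")
  msx <- sum(apply(Wtr, 2, var))
  if (msx == 0) stop("all markers monomorphic in the training set")
  S_beta <- vy * r2_prior * (df_beta + 2) / (msx * pi0)
  df_e <- 5
  S_e <- vy * (1 - r2_prior) * (df_e + 2)
  set.seed(seed)
  res <- bayesb_gibbs(yt, Wtr, as.integer(iters), as.integer(burnin),
                      as.integer(thin), df_beta, S_beta, pi0, p0,
                      df_e, S_e)
  eff <- setNames(drop(res$beta), colnames(X))
  gh <- drop(W %*% res$beta)
  names(gh) <- rownames(X)
  structure(list(effect = eff, inclusion = setNames(drop(res$inclusion),
                                                    colnames(X)),
                 mu = res$mu, g = gh, sigma2_e = res$sigma2_e,
                 pi = res$pi, model = "bayesb"),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("marker_effects (%s): %d markers, mu = %.4g\n",
              x$model, length(x$effect), x$mu))
  invisible(x)
}

#' Replicated k-fold cross-validated prediction ability
#'
#' For each replication a fresh random partition of individuals into
#' `folds` folds; the model is refit on the training folds (variance
#' components re-estimated, no leakage) and genetic values are
#' predicted for the held-out individuals.  Prediction ability is the
#' Pearson correlation between observed phenotypes and predicted
#' genetic values, computed per fold and averaged (set
#' `pooled = TRUE` to correlate all held-out predictions at once).
#'
#' @param y named phenotype vector.
#' @param g complete [geno_matrix()] (rrblup/bayesb) — may be omitted
#'   for gblup if `K` is given.
#' @param model `"gblup"`, `"rrblup"` or `"bayesb"`.
#' @param K kinship matrix (gblup; default [kinship()] of `g`).
#' @param folds,reps cross-validation layout (default 5 x 10).
#' @param seed integer RNG seed.
#' @param pooled correlate pooled held-out predictions instead of
#'   per-fold.
#' @param ... passed to the model fitter (e.g. BayesB chain settings).
#' @return A `cv_report` list: `ability` (mean), `per_fold`
#'   (data.frame rep x fold x ability), `model`, `folds`, `reps`,
#'   `seed`.
#' @export
cross_validate <- function(y, g = NULL, model = c("gblup", "rrblup",
                                                  "bayesb"),
                           K = NULL, folds = 5, reps = 10, seed = 1,
                           pooled = FALSE, ...) {
  model <- match.arg(model)
  if (model == "gblup" && is.null(K)) {
    if (is.null(g)) stop("gblup needs g or K")
    K <- kinship(g)
  }
  n <- if (!is.null(K)) nrow(K) else nrow(g$X)
  if (!is.null(g) && inherits(g, "geno_matrix"))
    y <- align_phenotype(y, g)
  y <- as.numeric(y)
  if (length(y) != n) stop("y must have one value per individual")
  if (n < folds) stop("need at least as many individuals as folds")
  set.seed(seed)
  rows <- list()
  pooled_rows <- list()
  for (rp in seq_len(reps)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    for (fd in seq_len(folds)) {
      test <- which(fold_id == fd)
      train <- which(fold_id != fd)
      if (sd(y[test]) == 0) {
        warning("constant held-out phenotype in rep ", rp, " fold ",
                fd, "; fold skipped")
        next
      }
      gh <- switch(model,
        gblup = fit_gblup(y[train], K, train = train)$g,
        rrblup = fit_rrblup(y[train], g, train = train)$g,
        bayesb = fit_bayesb(y[train], g, train = train,
                            seed = seed + 1000L * rp + fd, ...)$g)
      rows[[length(rows) + 1]] <- data.frame(
        rep = rp, fold = fd, ability = cor(y[test], gh[test]))
      pooled_rows[[length(pooled_rows) + 1]] <-
        data.frame(rep = rp, obs = y[test], pred = gh[test])
    }
  }
  per_fold <- do.call(rbind, rows)
  ability <- if (pooled) {
    pl <- do.call(rbind, pooled_rows)
    mean(vapply(split(pl, pl$rep),
                function(d) cor(d$obs, d$pred), numeric(1)))
  } else mean(per_fold$ability)
  structure(list(ability = ability, per_fold = per_fold, model = model,
                 folds = folds, reps = reps, seed = seed,
                 pooled = pooled),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report: %s, %d-fold x %d rep(s), mean prediction ability = %.3f\n",
    x$model, x$folds, x$reps, x$ability))
  invisible(x)
}

#' Rank marker effects against association hits
#'
#' Markers are ranked by absolute estimated effect (descending), with
#' ties broken by the association p-value and then marker order.  For
#' each association-significant marker the table reports its rank
#' among the prediction-model effects — agreement indicates the GWAS
#' hits also carry the largest whole-genome marker effects.
#'
#' @param effects a `marker_effects` object (RRBLUP or BayesB).
#' @param assoc an `assoc_table` with a logical `significant` column
#'   (e.g. from [bh_fdr()]) or all markers (then `top_k` defines the
#'   overlap set).
#' @param top_k overlap window for the summary (default number of
#'   significant markers).
#' @return list with `ranks` (data.frame marker, p, effect, rank) for
#'   the significant markers, `overlap_top_k`, `top_k`.
#' @export
rank_effects <- function(effects, assoc, top_k = NULL) {
  if (!inherits(effects, "marker_effects")) stop("need a marker_effects")
  shared <- intersect(names(effects$effect), assoc$marker)
  if (!length(shared)) stop("disjoint marker sets")
  eff <- effects$effect[shared]
  p <- assoc$p[match(shared, assoc$marker)]
  ord <- order(-abs(eff), p, seq_along(eff))
  rank <- integer(length(eff))
  rank[ord] <- seq_along(ord)
  names(rank) <- shared
  sig <- if (!is.null(assoc$significant))
    assoc$marker[assoc$significant] else assoc$marker
  sig <- intersect(sig, shared)
  if (is.null(top_k)) top_k <- max(1, length(sig))
  tab <- data.frame(marker = sig,
                    p = assoc$p[match(sig, assoc$marker)],
                    effect = eff[sig], rank = rank[sig],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  list(ranks = tab, overlap_top_k = sum(tab$rank <= top_k),
       top_k = top_k)
}

#' Prediction ability as a function of marker number
#'
#' For each subset size, random marker subsets are drawn and GBLUP
#' cross-validated ability is averaged over runs — small panels with
#' strong structure typically reach near-full ability with only tens
#' of markers, because few markers suffice to capture relatedness.
#'
#' @param y named phenotype vector.
#' @param g complete [geno_matrix()].
#' @param sizes marker subset sizes.
#' @param runs random subsets per size.
#' @param folds,reps cross-validation layout per run (default 5 x 1 to
#'   keep the grid affordable; the full-layout average over runs is the
#'   reported value).
#' @param seed integer RNG seed.
#' @return data.frame with `size`, `ability` (mean over runs), `se`
#'   (Monte-Carlo standard error).
#' @export
marker_subset_curve <- function(y, g, sizes = c(10, 25, 50, 100, 250,
                                                500),
                                runs = 100, folds = 5, reps = 1,
                                seed = 1) {
  check_geno(g, complete = TRUE)
  y <- align_phenotype(y, g)
  m <- ncol(g$X)
  if (any(sizes > m)) stop("subset size exceeds marker count")
  set.seed(seed)
  out <- lapply(sizes, function(s) {
    ab <- vapply(seq_len(runs), function(run) {
      sub <- sample.int(m, s)
      Ks <- kinship(g$X[, sub, drop = FALSE])
      cross_validate(y, model = "gblup", K = Ks, folds = folds,
                     reps = reps, seed = seed + 7919L * run)$ability
    }, numeric(1))
    data.frame(size = s, ability = mean(ab),
               se = sd(ab) / sqrt(length(ab)))
  })
  do.call(rbind, out)
}
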