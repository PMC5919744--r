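#' Fit the two-way random-effects model to multi-environment phenotypes
#'
#' Fits y_ijk = mu + G_i + E_j + GE_ij + e_ijk by REML with all effects
#' random except the intercept, the standard model for replicated
#' multi-environment trials.  The fit is delegated to
#' [lme4::lmer()]; for balanced data its REML estimates coincide with
#' the Henderson method-3 ANOVA estimators (this is exercised in the
#' test suite).  Variance components at the zero boundary are reported
#' as (numerically) zero.
#'
#' @param tbl long-format data.frame with columns `genotype`,
#'   `environment`, `replicate` and the trait column.
#' @param trait name of the trait column.
#' @return A list with
#'   * `vc`: a `variance_components` list with `sigma2_g`, `sigma2_ge`,
#'     `sigma2_e`, and design constants `e` (number of environments)
#'     and `r` (median replicate count);
#'   * `blups`: named per-genotype BLUPs of the genetic effect (sum to
#'     approximately zero);
#'   * `mu`: the fitted overall mean;
#'   * `fit`: the underlying `lmerMod` object.
#' @export
fit_two_way_random <- function(tbl, trait) {
  if (!trait %in% names(tbl)) stop("no column '", trait, "' in table")
  need <- c("genotype", "environment", "replicate")
  if (!all(need %in% names(tbl)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "))
  d <- data.frame(genotype = factor(tbl$genotype),
                  environment = factor(tbl$environment),
                  y = as.numeric(tbl[[trait]]))
  d <- d[!is.na(d$y), ]
  if (nlevels(droplevels(d$genotype)) < 2) stop("need >= 2 genotypes")
  if (nlevels(droplevels(d$environment)) < 2)
    stop("need >= 2 environments (sigma2_ge unidentifiable otherwise)")
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    y ~ 1 + (1 | genotype) + (1 | environment) +
      (1 | genotype:environment),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vcd <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) vcd$vcov[match(grp, vcd$grp)]
  e <- nlevels(droplevels(d$environment))
  r <- median(table(d$genotype, d$environment)[
    table(d$genotype, d$environment) > 0])
  vc <- variance_components(pick("genotype"),
                            pick("genotype:environment"),
                            pick("Residual"), r = r, e = e)
  blup <- lme4::ranef(fit)$genotype
  blups <- setNames(blup[, 1], rownames(blup))
  list(vc = vc, blups = blups, mu = as.numeric(lme4::fixef(fit)[1]),
       fit = fit)
}

#' Variance components of the two-way random model
#'
#' @param sigma2_g genetic variance.
#' @param sigma2_ge genotype-by-environment variance.
#' @param sigma2_e residual (plot error) variance.
#' @param r number of replications.
#' @param e number of environments.
#' @return A `variance_components` list.
#' @export
variance_components <- function(sigma2_g, sigma2_ge, sigma2_e, r, e) {
  v <- c(sigma2_g, sigma2_ge, sigma2_e)
  if (any(is.na(v))) stop("variance components must be numeric")
  if (any(v < -1e-8)) stop("variance components must be >= 0")
  if (r < 1 || e < 1) stop("design constants r and e must be >= 1")
  structure(list(sigma2_g = max(sigma2_g, 0),
                 sigma2_ge = max(sigma2_ge, 0),
                 sigma2_e = max(sigma2_e, 0), r = r, e = e),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance components: sigma2_g = %.4g, sigma2_ge = %.4g, sigma2_e = %.4g (r = %g, e = %g)\n",
    x$sigma2_g, x$sigma2_ge, x$sigma2_e, x$r, x$e))
  cat(sprintf("broad-sense H2 (entry-mean basis) = %.4f\n",
              heritability(x)))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma2_g / (sigma2_g + sigma2_ge / e + sigma2_e / (r e)).
#'
#' @param vc a [variance_components()].
#' @return H2 in \[0, 1\].
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  den <- vc$sigma2_g + vc$sigma2_ge / vc$e + vc$sigma2_e / (vc$r * vc$e)
  if (den <= 0) stop("all variance components are zero; H2 undefined")
  vc$sigma2_g / den
}

#' Genotypic and phenotypic trait correlations
#'
#' Genotypic correlations are Pearson correlations of per-genotype
#' BLUPs; phenotypic correlations are Pearson correlations of
#' per-genotype adjusted means.  Pairs with fewer than 3 shared
#' genotypes or a zero-variance trait get `NA`.
#'
#' @param blups_by_trait data.frame or matrix, genotypes x traits, of
#'   BLUPs (may contain NAs).
#' @param means_by_trait genotypes x traits adjusted means.
#' @return A list with matrices `genotypic` and `phenotypic`
#'   (symmetric, unit diagonal).
#' @export
trait_correlations <- function(blups_by_trait, means_by_trait) {
  corr <- function(M) {
    M <- as.matrix(M)
    t <- ncol(M)
    out <- diag(1, t)
    dimnames(out) <- list(colnames(M), colnames(M))
    for (i in seq_len(t)) for (j in seq_len(t)) {
      if (i >= j) next
      ok <- complete.cases(M[, c(i, j)])
      if (sum(ok) < 3 || sd(M[ok, i]) == 0 || sd(M[ok, j]) == 0) {
        out[i, j] <- out[j, i] <- NA
      } else {
        out[i, j] <- out[j, i] <- cor(M[ok, i], M[ok, j])
      }
    }
    out
  }
  list(genotypic = corr(blups_by_trait), phenotypic = corr(means_by_trait))
}

#' Per-genotype adjusted means from plot records
#'
#' Simple entry means over environments and replicates, usable as
#' BLUE-style input to association scans and genomic prediction.
#'
#' @param tbl long-format phenotype table.
#' @param trait trait column name.
#' @return Named numeric vector of per-genotype means.
#' @export
genotype_means <- function(tbl, trait) {
  if (!trait %in% names(tbl)) stop("no column '", trait, "' in table")
  mns <- tapply(as.numeric(tbl[[trait]]), as.character(tbl$genotype),
                mean, na.rm = TRUE)
  setNames(as.numeric(mns), names(mns))
}
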