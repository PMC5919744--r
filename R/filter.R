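#' Per-marker minor allele frequency
#'
#' MAF is computed over non-missing calls only (required when
#' genotyping-by-sequencing missingness reaches 19-77% per
#' individual).
#'
#' @param g a [geno_matrix()].
#' @return Numeric vector in \[0, 0.5\], one value per marker.
#' @export
compute_maf <- function(g) {
  check_geno(g)
  nn <- colSums(!is.na(g$X))
  if (any(nn == 0))
    stop("marker(s) with no non-missing calls: ",
         paste(head(colnames(g$X)[nn == 0], 3), collapse = ", "))
  p <- colMeans(g$X, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter markers by MAF and completeness
#'
#' Mirrors the standard pre-analysis rule for diversity panels: drop
#' markers with minor allele frequency below `maf_min` and (optionally)
#' any marker with at least one missing call, yielding the strict
#' "unimputed" data set.
#'
#' @param g a [geno_matrix()].
#' @param maf_min minimum MAF (default 0.05).
#' @param require_complete drop markers with any missing call?
#' @return A list with `geno` (filtered `geno_matrix`) and `report`, a
#'   `filter_report` list with `n_input`, `removed_maf`,
#'   `removed_missing`, `retained` (a marker failing both rules is
#'   counted under the MAF rule).
#' @export
filter_markers <- function(g, maf_min = 0.05, require_complete = FALSE) {
  check_geno(g)
  nn <- colSums(!is.na(g$X))
  p <- ifelse(nn > 0, colMeans(g$X, na.rm = TRUE) / 2, NA)
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf < maf_min
  fail_mis <- if (require_complete) colSums(is.na(g$X)) > 0 else
    rep(FALSE, ncol(g$X))
  keep <- !fail_maf & !fail_mis
  report <- structure(list(
    n_input = ncol(g$X),
    removed_maf = sum(fail_maf),
    removed_missing = sum(fail_mis & !fail_maf),
    retained = sum(keep)), class = "filter_report")
  if (!any(keep)) {
    warning("no markers survive the filter")
    return(list(geno = g[, keep], report = report))
  }
  list(geno = g[, keep], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d markers in; %d removed by MAF, %d by missingness; %d retained\n",
    x$n_input, x$removed_maf, x$removed_missing, x$retained))
  invisible(x)
}

#' Impute missing dosages
#'
#' A declared, simplified surrogate for haplotype-model imputers
#' (fastPHASE/BEAGLE-class HMMs are not reimplemented).  Two methods:
#' `"frequency"` draws each missing call from the marker's empirical
#' dosage distribution; `"knn_window"` finds, for each missing call,
#' the `k` individuals most concordant with the target over the `w`
#' nearest flanking markers on the same chromosome and imputes the
#' majority dosage among them (frequency-weighted draw on ties).  The
#' pipeline contract downstream stages rely on is only: a complete
#' matrix whose non-missing entries are unchanged.
#'
#' @param g a [geno_matrix()].
#' @param method `"frequency"` or `"knn_window"`.
#' @param w window size in markers (knn_window).
#' @param k number of nearest neighbours (knn_window).
#' @param seed integer RNG seed (tie-breaks and frequency draws).
#' @return A complete `geno_matrix`.
#' @export
impute_missing <- function(g, method = c("knn_window", "frequency"),
                           w = 20, k = 5, seed = 1) {
  method <- match.arg(method)
  check_geno(g)
  if (!anyNA(g$X)) return(g)
  nn <- colSums(!is.na(g$X))
  if (any(nn == 0))
    stop("cannot impute marker(s) with no observed calls: ",
         paste(head(colnames(g$X)[nn == 0], 3), collapse = ", "))
  set.seed(seed)
  X <- g$X
  if (method == "frequency") {
    for (j in which(colSums(is.na(X)) > 0)) {
      obs <- X[!is.na(X[, j]), j]
      miss <- which(is.na(X[, j]))
      X[miss, j] <- sample(obs, length(miss), replace = TRUE)
    }
  } else {
    X <- impute_knn_window(g, w, k)
  }
  geno_matrix(X, g$map, ids = rownames(g$X))
}

impute_knn_window <- function(g, w, k) {
  X <- g$X
  out <- X
  chroms <- g$map$chrom
  for (j in which(colSums(is.na(X)) > 0)) {
    same <- which(chroms == chroms[j] & seq_along(chroms) != j)
    if (!length(same)) {
      win <- integer(0)
    } else {
      win <- same[order(abs(g$map$pos[same] - g$map$pos[j]))]
      win <- win[seq_len(min(w, length(win)))]
    }
    miss <- which(is.na(X[, j]))
    donors <- which(!is.na(X[, j]))
    obs <- X[donors, j]
    for (i in miss) {
      if (length(win)) {
        diffs <- abs(sweep(X[donors, win, drop = FALSE], 2, X[i, win]))
        dist <- rowMeans(diffs, na.rm = TRUE)
        dist[is.nan(dist)] <- Inf
      } else dist <- rep(Inf, length(donors))
      if (all(!is.finite(dist))) {
        # no overlapping window calls: fall back to a frequency draw
        out[i, j] <- sample(obs, 1)
        next
      }
      kk <- min(k, sum(is.finite(dist)))
      nb <- order(dist)[seq_len(kk)]
      tab <- table(obs[nb])
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1) out[i, j] <- as.numeric(top)
      else {
        # tie: draw among tied dosages weighted by marker frequency
        freq <- table(factor(obs, levels = top))
        wts <- as.numeric(freq) + 1
        out[i, j] <- as.numeric(sample(top, 1, prob = wts))
      }
    }
  }
  out
}
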