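#' Pairwise linkage disequilibrium from unphased dosages
#'
#' Haplotype frequencies are estimated by the standard two-locus EM
#' (the only phase-ambiguous class is the double heterozygote),
#' converged to 1e-10.  With p_a and p_b the alternate-allele
#' frequencies and p_ab the alt-alt haplotype frequency,
#' D = p_ab - p_a p_b, the signed correlation is
#' r = D / sqrt(p_a (1-p_a) p_b (1-p_b)) and r2 = r^2.  The sign
#' convention is fixed by the reference allele in the marker map, so r
#' is comparable across subpopulations.
#'
#' @param g a [geno_matrix()].
#' @param pairs two-column integer matrix of marker column indices.
#' @return data.frame with one row per pair: marker ids, chromosomes,
#'   `dist_bp` (NA for inter-chromosomal pairs), `p_a`, `p_b`, `p_ab`,
#'   `D`, `r`, `r2`.
#' @export
pairwise_ld <- function(g, pairs) {
  check_geno(g)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  out <- data.frame(
    marker1 = colnames(g$X)[pairs[, 1]],
    marker2 = colnames(g$X)[pairs[, 2]],
    chrom1 = g$map$chrom[pairs[, 1]],
    chrom2 = g$map$chrom[pairs[, 2]],
    dist_bp = ifelse(g$map$chrom[pairs[, 1]] == g$map$chrom[pairs[, 2]],
                     abs(g$map$pos[pairs[, 1]] - g$map$pos[pairs[, 2]]),
                     NA_integer_),
    p_a = NA_real_, p_b = NA_real_, p_ab = NA_real_,
    D = NA_real_, r = NA_real_, r2 = NA_real_,
    stringsAsFactors = FALSE)
  for (idx in seq_len(nrow(pairs))) {
    d1 <- g$X[, pairs[idx, 1]]
    d2 <- g$X[, pairs[idx, 2]]
    ok <- !is.na(d1) & !is.na(d2)
    est <- em_haplotype_freqs(d1[ok], d2[ok])
    out$p_a[idx] <- est$p_a; out$p_b[idx] <- est$p_b
    out$p_ab[idx] <- est$p_ab; out$D[idx] <- est$D
    out$r[idx] <- est$r; out$r2[idx] <- est$r^2
  }
  out
}

# two-locus EM on dosage pairs; returns alt-allele and alt-alt
# haplotype frequencies.  Haplotype order: RR, RA, AR, AA
# (R = reference, A = alternate).
em_haplotype_freqs <- function(d1, d2, tol = 1e-10, max_iter = 1000) {
  if (length(d1) < 2) stop("need >= 2 complete genotype pairs")
  if (sd(d1) == 0 || sd(d2) == 0)
    stop("monomorphic marker; LD undefined")
  cnt <- table(factor(d1, levels = 0:2), factor(d2, levels = 0:2))
  n_hap <- 2 * length(d1)
  # fixed haplotype counts from unambiguous genotype classes
  fixRR <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  fixRA <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3]
  fixAR <- 2 * cnt[3, 1] + cnt[2, 1] + cnt[3, 2]
  fixAA <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  ndh <- cnt[2, 2]                       # double heterozygotes
  p_a <- mean(d1) / 2
  p_b <- mean(d2) / 2
  # start at linkage equilibrium
  h <- c(RR = (1 - p_a) * (1 - p_b), RA = (1 - p_a) * p_b,
         AR = p_a * (1 - p_b), AA = p_a * p_b)
  h <- pmax(h, 1e-12); h <- h / sum(h)
  for (it in seq_len(max_iter)) {
    wAA <- h["RR"] * h["AA"]
    wRA <- h["RA"] * h["AR"]
    frac <- if (wAA + wRA > 0) wAA / (wAA + wRA) else 0.5
    new <- c(fixRR + ndh * frac, fixRA + ndh * (1 - frac),
             fixAR + ndh * (1 - frac), fixAA + ndh * frac) / n_hap
    names(new) <- names(h)
    if (max(abs(new - h)) < tol) { h <- new; break }
    h <- new
  }
  p_ab <- unname(h["AA"])
  D <- p_ab - p_a * p_b
  r <- D / sqrt(p_a * (1 - p_a) * p_b * (1 - p_b))
  list(p_a = p_a, p_b = p_b, p_ab = p_ab, D = D,
       r = unname(r), iterations = it)
}

#' Intra-chromosomal marker pairs within a separation window
#'
#' @param g a [geno_matrix()].
#' @param max_sep maximum marker-index separation (adjacent pairs have
#'   separation 1).
#' @param chromosome optional chromosome id to restrict to.
#' @return Two-column matrix of marker column indices.
#' @export
adjacent_pairs <- function(g, max_sep = 1, chromosome = NULL) {
  check_geno(g)
  chroms <- unique(g$map$chrom)
  if (!is.null(chromosome)) chroms <- intersect(chroms, chromosome)
  out <- list()
  for (cc in chroms) {
    jj <- which(g$map$chrom == cc)
    for (s in seq_len(max_sep)) {
      if (length(jj) <= s) next
      out[[length(out) + 1]] <-
        cbind(jj[seq_len(length(jj) - s)], jj[-seq_len(s)])
    }
  }
  do.call(rbind, out)
}

#' Background (inter-chromosomal) LD level
#'
#' The chance level of LD between physically unlinked markers,
#' estimated as the 95th percentile (configurable) of r2 over randomly
#' sampled inter-chromosomal marker pairs.  Used as the horizontal
#' threshold against which LD decay is judged.
#'
#' @param g a [geno_matrix()] with >= 2 chromosomes.
#' @param n_pairs number of inter-chromosomal pairs to sample.
#' @param seed integer RNG seed.
#' @param percentile quantile of the inter-chromosomal r2 distribution
#'   (default 0.95).
#' @return Scalar background r2.
#' @export
background_ld <- function(g, n_pairs = 5000, seed = 1,
                          percentile = 0.95) {
  check_geno(g)
  if (length(unique(g$map$chrom)) < 2)
    stop("background LD needs >= 2 chromosomes")
  set.seed(seed)
  m <- ncol(g$X)
  chrom <- g$map$chrom
  got <- 0L
  pr <- matrix(0L, 0, 2)
  while (got < n_pairs) {
    cand <- cbind(sample.int(m, n_pairs, replace = TRUE),
                  sample.int(m, n_pairs, replace = TRUE))
    cand <- cand[chrom[cand[, 1]] != chrom[cand[, 2]], , drop = FALSE]
    pr <- rbind(pr, cand)
    got <- nrow(pr)
  }
  pr <- pr[seq_len(n_pairs), , drop = FALSE]
  ld <- pairwise_ld(g, pr)
  unname(quantile(ld$r2, percentile, na.rm = TRUE, type = 7))
}

#' Expected r2 under the Hill-Weir drift model
#'
#' @param d distance in bp.
#' @param rho recombination-rate scale parameter (per bp).
#' @param n number of sampled individuals.
#' @return Expected r2 at each distance.
#' @export
hill_weir_r2 <- function(d, rho, n) {
  C <- rho * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit an LD-decay curve and locate its background intersection
#'
#' Fits the Hill-Weir expectation of r2 as a function of distance by
#' nonlinear least squares to intra-chromosomal (distance, r2) pairs,
#' then solves numerically for the distance at which the fitted curve
#' crosses the background LD level — the maximum distance of genuine
#' linkage.  If the curve never crosses the background within the
#' observed distance range, the intersection is flagged undefined.
#'
#' @param g a [geno_matrix()].
#' @param chromosome chromosome id(s) to use; default all.
#' @param background background r2 level (from [background_ld()]).
#' @param max_sep marker-index separation window for pair generation.
#' @return A `decay_curve` list: `rho`, `n`, `fitted` (function of
#'   distance), `intersection_bp` (NA if undefined), `has_intersection`,
#'   `pairs` (the LD table used).
#' @export
ld_decay <- function(g, chromosome = NULL, background, max_sep = 10) {
  check_geno(g)
  pr <- adjacent_pairs(g, max_sep = max_sep, chromosome = chromosome)
  if (is.null(pr) || nrow(pr) < 50)
    stop("need >= 50 intra-chromosomal pairs to fit a decay curve")
  ld <- pairwise_ld(g, pr)
  ld <- ld[!is.na(ld$r2) & !is.na(ld$dist_bp), ]
  n <- nrow(g$X)
  start <- list(rho = 1 / max(1, median(ld$dist_bp)))
  fit <- tryCatch(
    nls(r2 ~ hill_weir_r2(dist_bp, rho, n), data = ld, start = start,
        algorithm = "port", lower = list(rho = 1e-14),
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e)
      stop("LD decay fit did not converge: ", conditionMessage(e),
           "; residual sd of null fit = ", signif(sd(ld$r2), 3),
           call. = FALSE))
  rho <- coef(fit)[["rho"]]
  f <- function(d) hill_weir_r2(d, rho, n)
  # the fitted curve is parametric: search for the background crossing
  # over the whole chromosome span, not just observed pair distances
  ix <- decay_intersection(f, background, c(1, max(g$map$pos)))
  structure(list(rho = rho, n = n, fitted = f,
                 intersection_bp = ix$where,
                 has_intersection = ix$crosses, pairs = ld),
            class = "decay_curve")
}

#' Where a decay curve crosses the background LD level
#'
#' @param curve_fn decreasing function of distance returning r2.
#' @param background background r2 level.
#' @param range length-2 numeric search interval (bp).
#' @return list with `crosses` (logical) and `where` (bp, NA when the
#'   curve stays above or below the background over the interval).
#' @export
decay_intersection <- function(curve_fn, background, range) {
  lo <- curve_fn(range[1]) - background
  hi <- curve_fn(range[2]) - background
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    return(list(crosses = FALSE, where = NA_real_))
  root <- uniroot(function(d) curve_fn(d) - background,
                  interval = range, tol = 1)
  list(crosses = TRUE, where = root$root)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("decay_curve: Hill-Weir rho = %.3g (n = %d), %d pairs\n",
              x$rho, x$n, nrow(x$pairs)))
  if (x$has_intersection)
    cat(sprintf("crosses background at ~%.1f kbp\n",
                x$intersection_bp / 1e3))
  else cat("does not cross the background level (flagged)\n")
  invisible(x)
}

#' Persistence of linkage phase between two samples
#'
#' Computes the signed LD correlation r for the same marker pairs in
#' two subpopulation genotype matrices sharing a marker map (allele
#' orientation fixed by the shared reference allele), then correlates
#' the paired r values.  Pairs are ordered by physical distance and the
#' correlation is averaged within groups of `bin_size` pairs, the
#' convention for comparing samples with unequal marker information.
#' A correlation near 1 means marker effects transfer between the
#' samples; near 0 means phases are scrambled.
#'
#' @param g_a,g_b [geno_matrix()] objects with identical marker maps
#'   (e.g. cluster subsets of one panel).
#' @param bin_size pairs per distance bin.
#' @param max_sep marker-index separation window for pair generation.
#' @return A list with `overall` (mean of per-bin correlations),
#'   `bins` (data.frame: bin, mean distance, correlation, n), and
#'   `pairs` (r_a, r_b, dist_bp per pair).
#' @export
phase_persistence <- function(g_a, g_b, bin_size = 50, max_sep = 5) {
  check_geno(g_a); check_geno(g_b)
  if (!identical(g_a$map[c("chrom", "pos")], g_b$map[c("chrom", "pos")]))
    stop("the two samples must share one marker map")
  pr <- adjacent_pairs(g_a, max_sep = max_sep)
  ld_a <- pairwise_ld_safe(g_a, pr)
  ld_b <- pairwise_ld_safe(g_b, pr)
  ok <- !is.na(ld_a$r) & !is.na(ld_b$r)
  d <- data.frame(dist_bp = ld_a$dist_bp[ok], r_a = ld_a$r[ok],
                  r_b = ld_b$r[ok])
  d <- d[order(d$dist_bp), ]
  np <- nrow(d)
  if (np < 2) stop("not enough informative shared pairs")
  if (np < bin_size) {
    warning("fewer shared pairs (", np, ") than bin_size; using one bin")
    bin <- rep(1L, np)
  } else {
    bin <- ceiling(seq_len(np) / bin_size)
    # fold a short trailing bin into the previous one
    if (sum(bin == max(bin)) < bin_size / 2 && max(bin) > 1)
      bin[bin == max(bin)] <- max(bin) - 1L
  }
  d$bin <- bin
  bins <- do.call(rbind, lapply(split(d, d$bin), function(b) {
    data.frame(bin = b$bin[1], dist_bp = mean(b$dist_bp),
               correlation = if (nrow(b) >= 3 && sd(b$r_a) > 0 &&
                                 sd(b$r_b) > 0)
                 cor(b$r_a, b$r_b) else NA_real_,
               n = nrow(b))
  }))
  rownames(bins) <- NULL
  list(overall = mean(bins$correlation, na.rm = TRUE), bins = bins,
       pairs = d)
}

# pairwise_ld that returns NA rows for monomorphic markers instead of
# erroring (subpopulation subsets routinely fix alleles)
pairwise_ld_safe <- function(g, pairs) {
  mono <- apply(g$X, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || sd(x) == 0
  })
  keep <- !mono[pairs[, 1]] & !mono[pairs[, 2]]
  out <- data.frame(dist_bp = rep(NA_real_, nrow(pairs)),
                    r = NA_real_, r2 = NA_real_)
  if (any(keep)) {
    ld <- pairwise_ld(g, pairs[keep, , drop = FALSE])
    out$dist_bp[keep] <- ld$dist_bp
    out$r[keep] <- ld$r
    out$r2[keep] <- ld$r2
  }
  out$dist_bp <- ifelse(g$map$chrom[pairs[, 1]] == g$map$chrom[pairs[, 2]],
                        abs(g$map$pos[pairs[, 1]] - g$map$pos[pairs[, 2]]),
                        NA_real_)
  out
}
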