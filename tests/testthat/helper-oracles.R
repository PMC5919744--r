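# Shared fixtures and independent oracles used across test files.
# Everything is generated in code; no stored fixtures.

# small structured panel used by several tests
make_panel <- function(n = 120, mpc = 150, chroms = 3, K = 3, F = 0.2,
                       ld = 0.9, h2 = 0.8, n_qtl = 5, seed = 1) {
  simulate_population(
    sim_config(n_individuals = n, n_chromosomes = chroms,
               markers_per_chromosome = mpc, n_clusters = K, F = F,
               ld_correlation = ld, h2 = h2, n_qtl = n_qtl),
    seed = seed)
}

# entry-mean phenotype with a target entry-mean heritability
mean_phenotype <- function(g_values, h2, ids, seed = 1) {
  set.seed(seed)
  if (h2 == 0) {
    y <- rnorm(length(ids))
  } else {
    y <- g_values + rnorm(length(g_values),
                          0, sd(g_values) * sqrt(1 / h2 - 1))
  }
  setNames(y, ids)
}

# Weir-Cockerham-style FST: variance of cluster allele frequencies,
# corrected for binomial sampling noise, over mean p(1-p)
fst_estimate <- function(X, labels) {
  num <- den <- 0
  for (j in seq_len(ncol(X))) {
    pk <- tapply(X[, j], labels, mean) / 2
    nk <- tapply(X[, j], labels, length)
    pbar <- mean(pk)
    if (pbar <= 0 || pbar >= 1) next
    num <- num + (var(pk) - mean(pk * (1 - pk) / (2 * nk)))
    den <- den + pbar * (1 - pbar)
  }
  num / den
}

# adjusted Rand index (brute-force contingency form)
adj_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Henderson method-3 ANOVA estimators for the balanced two-way random
# model (closed-form mean-squares oracle)
method3_components <- function(tbl, trait) {
  d <- data.frame(G = factor(tbl$genotype), E = factor(tbl$environment),
                  y = tbl[[trait]])
  r <- length(unique(tbl$replicate))
  e <- nlevels(d$E)
  ms <- anova(aov(y ~ G + E + G:E, data = d))[["Mean Sq"]]
  names(ms) <- c("G", "E", "GE", "err")
  list(sigma2_e = ms[["err"]],
       sigma2_ge = (ms[["GE"]] - ms[["err"]]) / r,
       sigma2_g = (ms[["G"]] - ms[["GE"]]) / (r * e))
}

# genotypes assembled from explicit haplotype draws (LD truth ledger)
panel_from_haplotypes <- function(n, hapfreq, seed = 1) {
  set.seed(seed)
  haps <- sample(1:4, 2 * n, TRUE, prob = hapfreq)  # AB, Ab, aB, ab
  h1 <- haps[1:n]
  h2 <- haps[(n + 1):(2 * n)]
  alt1 <- function(h) as.integer(h %in% c(3, 4))
  alt2 <- function(h) as.integer(h %in% c(2, 4))
  g <- geno_matrix(cbind(alt1(h1) + alt1(h2), alt2(h1) + alt2(h2)),
                   data.frame(chrom = "C1", pos = c(100, 200)))
  list(geno = g,
       p_ab = mean(c(alt1(h1) * alt2(h1), alt1(h2) * alt2(h2))),
       p_a = mean(c(alt1(h1), alt1(h2))),
       p_b = mean(c(alt2(h1), alt2(h2))))
}
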