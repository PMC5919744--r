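#' Configuration for the synthetic panel generator
#'
#' Defaults describe a gene-bank-scale diversity panel: 174 individuals
#' in 5 differentiated clusters on 9 chromosomes, genotyping-by-
#' sequencing-like marker density and per-individual missingness
#' between 19.02% and 76.73%, phenotyped in 6 environments with 2
#' replicates.
#'
#' @param n_individuals panel size.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers simulated per chromosome.
#' @param chromosome_length_bp chromosome length in bp.
#' @param n_clusters number of differentiated clusters K.
#' @param F Balding-Nichols drift parameter in (0, 1); 0 gives a
#'   panmictic panel.
#' @param ld_correlation correlation of adjacent marker alleles on a
#'   haplotype at the expected marker spacing, in \[0, 1); attenuates
#'   with bp gap.
#' @param maf_floor minimum realized minor allele frequency; markers
#'   below it are re-simulated.
#' @param missing_range length-2 vector, the low/high per-individual
#'   missing fraction for [inject_missingness()].
#' @param n_environments,n_replicates phenotyping design constants.
#' @param n_qtl number of additive QTL underlying the simulated trait.
#' @param h2 target broad-sense heritability on an entry-mean basis.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 174, n_chromosomes = 9,
                       markers_per_chromosome = 1200,
                       chromosome_length_bp = 4e7,
                       n_clusters = 5, F = 0.2, ld_correlation = 0.9,
                       maf_floor = 0.05,
                       missing_range = c(0.1902, 0.7673),
                       n_environments = 6, n_replicates = 2,
                       n_qtl = 10, h2 = 0.8) {
  cfg <- list(n_individuals = n_individuals, n_chromosomes = n_chromosomes,
              markers_per_chromosome = markers_per_chromosome,
              chromosome_length_bp = chromosome_length_bp,
              n_clusters = n_clusters, F = F,
              ld_correlation = ld_correlation, maf_floor = maf_floor,
              missing_range = missing_range,
              n_environments = n_environments, n_replicates = n_replicates,
              n_qtl = n_qtl, h2 = h2)
  stopifnot(n_individuals >= 2, n_chromosomes >= 1,
            markers_per_chromosome >= 2, n_clusters >= 1,
            F >= 0, F < 1, ld_correlation >= 0, ld_correlation < 1,
            maf_floor >= 0, maf_floor < 0.5,
            length(missing_range) == 2)
  if (missing_range[1] < 0 || missing_range[2] >= 1 ||
      missing_range[1] > missing_range[2])
    stop("missing_range must satisfy 0 <= low <= high < 1")
  if (n_clusters > n_individuals)
    stop("n_clusters cannot exceed n_individuals")
  structure(cfg, class = "sim_config")
}

#' Simulate a structured genotype panel with known truth
#'
#' Cluster allele frequencies follow the Balding-Nichols model: for a
#' marker with ancestral frequency p, each cluster draws its frequency
#' from Beta(p(1-F)/F, (1-p)(1-F)/F), so allele-frequency divergence
#' among clusters has expectation F (Wright's FST).  Along each
#' chromosome, haplotypes follow a first-order Markov copy process on a
#' latent uniform variable: the latent value is copied from the previous
#' marker with probability `ld_correlation^(gap/expected_gap)`, which
#' yields distance-decaying LD while preserving marginal frequencies.
#' Dosages are the sum of two independent haplotypes; phase is
#' discarded.  QTL effects are drawn once and rescaled so the genetic
#' variance of the panel equals the truth value exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return A list with elements `geno` (a complete [geno_matrix()], no
#'   missing values, every marker MAF >= `maf_floor`) and `truth`, a
#'   `sim_truth` list carrying `cluster_labels`, `F`, `qtl_index`,
#'   `qtl_effect`, the genetic values `g`, true variance components
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`, and `seed`.
#' @export
simulate_population <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_clusters > config$n_individuals)
    stop("n_clusters cannot exceed n_individuals")
  set.seed(seed)
  n <- config$n_individuals
  K <- config$n_clusters
  mpc <- config$markers_per_chromosome
  m <- config$n_chromosomes * mpc

  labels <- sample(rep(seq_len(K), length.out = n))
  chrom <- rep(sprintf("C%02d", seq_len(config$n_chromosomes)), each = mpc)
  pos <- unlist(lapply(seq_len(config$n_chromosomes), function(cc)
    sort(sample.int(config$chromosome_length_bp, mpc))))

  p_anc <- runif(m, 0.05, 0.95)
  p_clu <- draw_cluster_freqs(p_anc, K, config$F)

  X <- matrix(0, n, m)
  gap_ref <- config$chromosome_length_bp / mpc
  for (cc in seq_len(config$n_chromosomes)) {
    jj <- which(chrom == sprintf("C%02d", cc))
    gaps <- diff(pos[jj])
    copy_p <- if (config$ld_correlation == 0) rep(0, length(gaps)) else
      config$ld_correlation ^ (gaps / gap_ref)
    for (h in 1:2) {
      U <- matrix(NA_real_, n, length(jj))
      U[, 1] <- runif(n)
      for (k in seq_along(gaps)) {
        keep <- runif(n) < copy_p[k]
        U[, k + 1] <- ifelse(keep, U[, k], runif(n))
      }
      P <- p_clu[labels, jj, drop = FALSE]
      X[, jj] <- X[, jj] + (U < P)
    }
  }

  # generation-time rejection: re-simulate markers under the MAF floor
  for (round in 1:50) {
    p_hat <- colMeans(X) / 2
    low <- which(pmin(p_hat, 1 - p_hat) < config$maf_floor)
    if (!length(low)) break
    p_anc[low] <- runif(length(low), 0.2, 0.8)
    p_new <- draw_cluster_freqs(p_anc[low], K, config$F)
    X[, low] <- matrix(
      rbinom(n * length(low), 1, p_new[labels, , drop = FALSE]) +
        rbinom(n * length(low), 1, p_new[labels, , drop = FALSE]),
      n, length(low))
  }
  p_hat <- colMeans(X) / 2
  if (any(pmin(p_hat, 1 - p_hat) < config$maf_floor))
    stop("could not satisfy maf_floor after 50 rejection rounds")

  g <- geno_matrix(X, data.frame(chrom = chrom, pos = pos,
                                 ref = "A", alt = "T"))

  qtl <- sort(sample.int(m, config$n_qtl))
  eff <- rnorm(config$n_qtl)
  gv <- drop(X[, qtl, drop = FALSE] %*% eff)
  sigma2_g <- if (config$h2 > 0) 1 else 0
  if (sd(gv) > 0 && sigma2_g > 0) {
    eff <- eff * sqrt(sigma2_g / var(gv))
    gv <- drop(X[, qtl, drop = FALSE] %*% eff)
  } else {
    eff[] <- 0
    gv[] <- 0
  }
  noise <- noise_variances(sigma2_g, config$h2, config$n_environments,
                           config$n_replicates)
  truth <- structure(list(
    cluster_labels = labels, F = config$F,
    qtl_index = qtl, qtl_effect = eff, g = gv - mean(gv),
    sigma2_g = sigma2_g, sigma2_ge = noise$sigma2_ge,
    sigma2_e = noise$sigma2_e, seed = seed), class = "sim_truth")
  list(geno = g, truth = truth)
}

# Balding-Nichols cluster frequencies; F = 0 collapses to the ancestral
# frequency.  Clamped away from fixation so markers stay polymorphic.
draw_cluster_freqs <- function(p_anc, K, F) {
  m <- length(p_anc)
  if (F == 0) {
    p <- matrix(rep(p_anc, each = K), K, m)
  } else {
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    p <- matrix(rbeta(K * m, rep(a, each = K), rep(b, each = K)), K, m)
  }
  pmin(pmax(p, 0.01), 0.99)
}

# split target H2 into equal sigma2_ge = sigma2_e given design constants
noise_variances <- function(sigma2_g, h2, e, r) {
  if (h2 < 0 || h2 > 1) stop("target h2 must be in [0, 1]")
  if (h2 == 0) return(list(sigma2_ge = 1, sigma2_e = 1))
  if (h2 == 1) return(list(sigma2_ge = 0, sigma2_e = 0))
  s <- sigma2_g * (1 / h2 - 1) / (1 / e + 1 / (r * e))
  list(sigma2_ge = s, sigma2_e = s)
}

#' Inject per-individual missingness into a genotype matrix
#'
#' Each individual's missing fraction is drawn uniformly from
#' `missing_range` and calls are masked completely at random at that
#' rate, emulating the highly uneven per-genotype missingness of
#' genotyping-by-sequencing.  Columns that would become entirely
#' missing are resampled to retain at least one call.
#'
#' @param g a [geno_matrix()].
#' @param missing_range length-2 numeric, low/high missing fraction.
#' @param seed integer RNG seed.
#' @return A `geno_matrix` with masked calls; retained calls are
#'   unchanged.
#' @export
inject_missingness <- function(g, missing_range = c(0.1902, 0.7673),
                               seed = 1) {
  check_geno(g)
  if (missing_range[1] < 0 || missing_range[2] >= 1 ||
      missing_range[1] > missing_range[2])
    stop("missing_range must satisfy 0 <= low <= high < 1")
  set.seed(seed)
  n <- nrow(g$X); m <- ncol(g$X)
  rate <- runif(n, missing_range[1], missing_range[2])
  mask <- matrix(runif(n * m), n, m) < rate
  # no column may lose all its calls
  dead <- which(colSums(!mask & !is.na(g$X)) == 0)
  for (j in dead) {
    keep <- sample(which(!is.na(g$X[, j])), 1)
    mask[keep, j] <- FALSE
  }
  X <- g$X
  X[mask] <- NA
  geno_matrix(X, g$map, ids = rownames(g$X))
}

#' Simulate replicated multi-environment phenotypes
#'
#' Generates plot-level records under the two-way random model
#' y_ijk = mu + G_i + E_j + GE_ij + e_ijk, with the genetic values G_i
#' taken from the simulation truth (QTL sums, variance fixed exactly),
#' environment main effects drawn N(0, 1), interactions
#' N(0, sigma2_ge) and plot residuals N(0, sigma2_e).
#'
#' @param g a complete [geno_matrix()] (used for dimension checks; the
#'   genetic values are carried by `truth`).
#' @param truth a `sim_truth` from [simulate_population()].
#' @param config a [sim_config()] (design constants).
#' @param seed integer RNG seed.
#' @param trait name for the trait column.
#' @param mu overall mean.
#' @return Long-format data.frame with columns `genotype`,
#'   `environment`, `replicate`, `<trait>`.
#' @export
simulate_phenotypes <- function(g, truth, config = sim_config(), seed = 1,
                                trait = "trait", mu = 50) {
  check_geno(g)
  if (!inherits(truth, "sim_truth")) stop("truth must be a sim_truth")
  if (length(truth$g) != nrow(g$X))
    stop("truth genetic values do not match panel size")
  if (any(truth$qtl_index < 1 | truth$qtl_index > ncol(g$X)))
    stop("truth QTL indices out of range for this genotype matrix")
  set.seed(seed)
  n <- nrow(g$X); e <- config$n_environments; r <- config$n_replicates
  ids <- rownames(g$X)
  env <- sprintf("E%d", seq_len(e))
  d <- expand.grid(genotype = ids, environment = env,
                   replicate = seq_len(r), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  Ej <- rnorm(e, 0, 1)
  GE <- matrix(rnorm(n * e, 0, sqrt(truth$sigma2_ge)), n, e,
               dimnames = list(ids, env))
  eps <- rnorm(nrow(d), 0, sqrt(truth$sigma2_e))
  gi <- setNames(truth$g, ids)
  d[[trait]] <- mu + gi[d$genotype] + Ej[match(d$environment, env)] +
    GE[cbind(d$genotype, d$environment)] + eps
  rownames(d) <- NULL
  d
}

#' Write simulation truth as a JSON sidecar
#'
#' @param truth a `sim_truth`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
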