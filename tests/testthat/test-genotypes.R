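test_that("MAF is computed over non-missing calls", {
  g <- geno_matrix(cbind(a = c(0, 0, 1, 2), b = c(0, 0, 0, 0),
                         c = c(2, 2, 2, 1)),
                   data.frame(chrom = "C1", pos = c(10, 20, 30)))
  expect_equal(unname(compute_maf(g)), c(0.375, 0, 0.125))
  gna <- geno_matrix(cbind(c(0, NA, 1, 2)),
                     data.frame(chrom = "C1", pos = 1))
  expect_equal(unname(compute_maf(gna)), 0.5)
  gall <- geno_matrix(cbind(c(NA, NA), c(0, 1)),
                      data.frame(chrom = "C1", pos = 1:2))
  expect_error(compute_maf(gall), "no non-missing")
})

test_that("marker filtering applies MAF and completeness rules", {
  # 5-marker toy: one MAF=0.02 column (25 individuals), one column with
  # a missing call; require_complete keeps 3
  X <- matrix(1, 25, 5)
  X[, 1] <- c(1, rep(0, 24))            # MAF = 1/50 = 0.02
  X[, 2] <- rep(c(0, 2), length.out = 25)
  X[1, 3] <- NA                          # complete-case casualty
  X[, 4] <- rep(c(0, 1, 2), length.out = 25)
  X[, 5] <- rep(c(2, 0), length.out = 25)
  g <- geno_matrix(X, data.frame(chrom = "C1", pos = 1:5 * 100))
  fl <- filter_markers(g, maf_min = 0.05, require_complete = TRUE)
  expect_equal(fl$report$retained, 3)
  expect_equal(fl$report$removed_maf, 1)
  expect_equal(fl$report$removed_missing, 1)
  expect_equal(fl$report$removed_maf + fl$report$removed_missing +
                 fl$report$retained, fl$report$n_input)
  # identity when disabled
  fl0 <- filter_markers(g, maf_min = 0, require_complete = FALSE)
  expect_equal(ncol(fl0$geno$X), 5)
  # idempotence
  fl2 <- filter_markers(fl$geno, maf_min = 0.05, require_complete = TRUE)
  expect_identical(fl2$geno$X, fl$geno$X)
  expect_warning(filter_markers(g, maf_min = 0.49,
                                require_complete = TRUE),
                 "no markers")
})

test_that("VCF round trip preserves dosages, map and encoding", {
  sim <- make_panel(n = 30, mpc = 40, chroms = 2, seed = 13)
  gm <- inject_missingness(sim$geno, c(0.1, 0.3), seed = 2)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(gm, path, "vcf")
  back <- read_genotypes(path, "vcf")
  expect_equal(unname(back$X), unname(gm$X))
  expect_equal(back$map$chrom, gm$map$chrom)
  expect_equal(back$map$pos, gm$map$pos)
  # GT encoding spot checks straight off the file
  lines <- readLines(path)
  expect_true(any(grepl("\t\\./\\.", lines)))
  # dosage round trip too
  pd <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, pd, "dosage")
  back2 <- read_genotypes(pd, "dosage")
  expect_equal(unname(back2$X), unname(gm$X))
  expect_equal(geno_ids(back2), geno_ids(gm))
})

test_that("VCF round trips hold across random matrices", {
  # scaled down from an exhaustive 1000-matrix sweep for runtime
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    m <- sample(5:30, 1)
    X <- matrix(sample(c(0:2, NA), n * m, TRUE), n, m)
    X[1, ] <- 0                          # keep no column all-missing
    map <- data.frame(chrom = sample(c("C1", "C2"), m, TRUE),
                      pos = sample.int(1e6, m))
    g <- geno_matrix(X, map)
    path <- withr::local_tempfile(fileext = ".vcf")
    write_genotypes(g, path, "vcf")
    back <- read_genotypes(path, "vcf")
    expect_equal(unname(back$X), unname(g$X))
    expect_equal(back$map[c("chrom", "pos")], g$map[c("chrom", "pos")])
  }
})

test_that("multi-allelic records are dropped on read", {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2"), collapse = "\t"))
  rec <- function(pos, ref, alt, g1, g2)
    paste("C1", pos, ".", ref, alt, ".", "PASS", ".", "GT", g1, g2,
          sep = "\t")
  body <- c(vapply(1:9, function(i)
    rec(i * 10, "A", "T", "0/1", "1/1"), ""),
    rec(100, "A", "T,G", "0/1", "0/2"))      # triallelic
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(hdr, body), path)
  expect_message(g <- read_genotypes(path, "vcf"), "dropped 1")
  expect_equal(ncol(g$X), 9)
  expect_equal(unname(g$X[, 1]), c(1, 2))
})

test_that("duplicate positions and malformed files error", {
  expect_error(geno_matrix(cbind(c(0, 1), c(1, 2)),
                           data.frame(chrom = "C1", pos = c(5, 5))),
               "duplicate")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines("this is not a vcf", path)
  expect_error(read_genotypes(path, "vcf"), "malformed VCF")
  expect_error(read_genotypes("/nonexistent/file.vcf"), "not found")
})

test_that("imputation restores a complete matrix and beats the frequency baseline", {
  sim <- make_panel(n = 100, mpc = 250, chroms = 2, K = 1, F = 0,
                    ld = 0.9, seed = 17)
  gm <- inject_missingness(sim$geno, c(0.1, 0.1), seed = 3)
  masked <- is.na(gm$X)
  # identity on complete input
  expect_identical(impute_missing(sim$geno, "knn_window")$X, sim$geno$X)
  gk <- impute_missing(gm, "knn_window", w = 20, k = 5, seed = 4)
  gf <- impute_missing(gm, "frequency", seed = 4)
  expect_false(anyNA(gk$X))
  expect_false(anyNA(gf$X))
  # non-missing entries unchanged
  expect_identical(gk$X[!masked], gm$X[!masked])
  acc_k <- mean(gk$X[masked] == sim$geno$X[masked])
  acc_f <- mean(gf$X[masked] == sim$geno$X[masked])
  expect_gt(acc_k, acc_f)
  # determinism
  gk2 <- impute_missing(gm, "knn_window", w = 20, k = 5, seed = 4)
  expect_identical(gk$X, gk2$X)
  expect_error(impute_missing(gm, "hmm"), "arg")
})

test_that("impute + filter pipeline leaves every retained marker at MAF >= 0.05", {
  sim <- make_panel(n = 80, mpc = 200, chroms = 2, K = 2, seed = 19)
  gm <- inject_missingness(sim$geno, c(0.2, 0.6), seed = 5)
  gi <- impute_missing(gm, "knn_window", seed = 6)
  fl <- filter_markers(gi, maf_min = 0.05, require_complete = TRUE)
  expect_true(all(compute_maf(fl$geno) >= 0.05))
  expect_false(anyNA(fl$geno$X))
})
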