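#' Run the full analysis workflow from one configuration
#'
#' Orchestrates the stages in study order — simulate (or read inputs),
#' filter, impute, phenotype model, structure, LD, association,
#' prediction — writing each stage's outputs under `out_dir` plus a
#' JSON manifest (inputs, parameters, seeds, md5 checksums).  The
#' single global seed is expanded into fixed per-stage sub-seeds
#' (`seed + 1000 * stage_index`), so any stage can be rerun in
#' isolation and deterministic stages reproduce their checksums.
#'
#' @param config a list, or path to a YAML/JSON file, with elements:
#'   `out_dir`; either `simulate` (a list of [sim_config()] arguments,
#'   plus optional `inject_missingness = TRUE`) or `genotypes`
#'   (`path`, `format`) and optionally `phenotypes` (`path`); `stages`
#'   (character subset of `c("filter", "impute", "pheno", "structure",
#'   "ld", "gwas", "predict")`); optional per-stage parameter lists
#'   `filter`, `impute`, `structure`, `ld`, `gwas`, `predict`; `trait`
#'   (trait column name, default "trait").
#' @param seed global integer seed.
#' @return The manifest (list), invisibly written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, seed = 1) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config))
      yaml::read_yaml(config) else jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
  }
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% character(0)
  trait <- config$trait %||% "trait"
  sub_seed <- function(i) as.integer(seed + 1000L * i)
  artifacts <- list()
  add <- function(stage, path, params = NULL) {
    artifacts[[length(artifacts) + 1]] <<- list(
      stage = stage, path = basename(path),
      md5 = unname(tools::md5sum(path)), params = params)
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", stage))
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  truth <- NULL
  pheno <- NULL
  if (!is.null(config$simulate)) {
    simcfg <- do.call(sim_config, config$simulate[
      setdiff(names(config$simulate), "inject_missingness")])
    sim <- run_stage("simulate",
                     simulate_population(simcfg, seed = sub_seed(1)))
    geno <- sim$geno
    truth <- sim$truth
    pheno <- run_stage("simulate", simulate_phenotypes(
      geno, truth, simcfg, seed = sub_seed(2), trait = trait))
    if (isTRUE(config$simulate$inject_missingness))
      geno <- inject_missingness(geno, simcfg$missing_range,
                                 seed = sub_seed(3))
    write_genotypes(geno, file.path(out_dir, "genotypes.vcf"), "vcf")
    write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv"))
    write_sim_truth(truth, file.path(out_dir, "truth.json"))
    add("simulate", file.path(out_dir, "genotypes.vcf"),
        params = unclass(simcfg))
    add("simulate", file.path(out_dir, "phenotypes.tsv"))
    add("simulate", file.path(out_dir, "truth.json"))
  } else {
    geno <- run_stage("read", read_genotypes(config$genotypes$path,
                                             config$genotypes$format %||%
                                               "vcf"))
    if (!is.null(config$phenotypes))
      pheno <- read_phenotypes(config$phenotypes$path)
  }

  if ("filter" %in% stages) {
    prm <- config$filter %||% list()
    fl <- run_stage("filter", filter_markers(
      geno, maf_min = prm$maf_min %||% 0.05,
      require_complete = prm$require_complete %||% FALSE))
    geno <- fl$geno
    jsonlite::write_json(unclass(fl$report),
                         file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE)
    add("filter", file.path(out_dir, "filter_report.json"), prm)
  }
  if ("impute" %in% stages) {
    prm <- config$impute %||% list()
    geno <- run_stage("impute", impute_missing(
      geno, method = prm$method %||% "knn_window",
      w = prm$w %||% 20, k = prm$k %||% 5, seed = sub_seed(4)))
    write_genotypes(geno, file.path(out_dir, "genotypes_imputed.tsv"),
                    "dosage")
    add("impute", file.path(out_dir, "genotypes_imputed.tsv"), prm)
  }

  y <- NULL
  h2 <- NA_real_
  if ("pheno" %in% stages) {
    if (is.null(pheno)) stop("pheno stage needs phenotype data")
    fit <- run_stage("pheno", fit_two_way_random(pheno, trait))
    h2 <- heritability(fit$vc)
    y <- genotype_means(pheno, trait)
    df <- data.frame(genotype = names(fit$blups), blup = fit$blups,
                     mean = y[names(fit$blups)])
    data.table::fwrite(df, file.path(out_dir, "blups.tsv"), sep = "\t")
    jsonlite::write_json(
      c(unclass(fit$vc), list(H2 = h2)),
      file.path(out_dir, "variance_components.json"),
      auto_unbox = TRUE, digits = NA)
    add("pheno", file.path(out_dir, "blups.tsv"))
    add("pheno", file.path(out_dir, "variance_components.json"))
  }

  cl <- NULL
  if ("structure" %in% stages) {
    prm <- config$structure %||% list()
    cl <- run_stage("structure", find_clusters(
      geno, k_range = seq_len(prm$k_max %||% 8),
      n_pcs = prm$n_pcs %||% "auto", seed = sub_seed(5)))
    data.table::fwrite(
      data.frame(id = geno_ids(geno), cluster = cl$labels),
      file.path(out_dir, "clusters.tsv"), sep = "\t")
    add("structure", file.path(out_dir, "clusters.tsv"), prm)
  }

  if ("ld" %in% stages) {
    prm <- config$ld %||% list()
    bg <- run_stage("ld", background_ld(
      geno, n_pairs = prm$n_pairs %||% 2000, seed = sub_seed(6)))
    dc <- run_stage("ld", ld_decay(geno, background = bg,
                                   max_sep = prm$max_sep %||% 10))
    jsonlite::write_json(
      list(background_r2 = bg, rho = dc$rho,
           intersection_bp = dc$intersection_bp,
           has_intersection = dc$has_intersection),
      file.path(out_dir, "ld_summary.json"), auto_unbox = TRUE,
      digits = NA)
    add("ld", file.path(out_dir, "ld_summary.json"), prm)
  }

  assoc <- NULL
  if ("gwas" %in% stages) {
    if (is.null(y)) stop("gwas stage needs the pheno stage")
    prm <- config$gwas %||% list()
    check_geno(geno, complete = TRUE,
               what = "genotype matrix at scan time")
    assoc <- run_stage("gwas", emmax_scan(y, geno))
    assoc$significant <- bh_fdr(assoc$p, Q = prm$Q %||% 0.2)
    data.table::fwrite(assoc, file.path(out_dir, "gwas_emmax.tsv"),
                       sep = "\t")
    add("gwas", file.path(out_dir, "gwas_emmax.tsv"),
        c(prm, list(lambda = attr(assoc, "lambda"))))
  }

  if ("predict" %in% stages) {
    if (is.null(y)) stop("predict stage needs the pheno stage")
    prm <- config$predict %||% list()
    models <- prm$models %||% "gblup"
    cvres <- lapply(models, function(mdl) run_stage(
      paste0("predict:", mdl),
      cross_validate(y, geno, model = mdl,
                     folds = prm$folds %||% 5, reps = prm$reps %||% 10,
                     seed = sub_seed(7))))
    df <- data.frame(trait = trait, model = unlist(models),
                     ability = vapply(cvres, `[[`, 0, "ability"))
    data.table::fwrite(df, file.path(out_dir, "prediction.tsv"),
                       sep = "\t")
    add("predict", file.path(out_dir, "prediction.tsv"), prm)
  }

  manifest <- list(seed = seed, created = format(Sys.time()),
                   stages = stages, artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a file path")
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  if (is.null(config$simulate) && is.null(config$genotypes))
    stop("config needs either a 'simulate' block or 'genotypes'")
  if (!is.null(config$genotypes) &&
      !file.exists(config$genotypes$path %||% ""))
    stop("genotype file not found: ", config$genotypes$path)
  if (!is.null(config$phenotypes) &&
      !file.exists(config$phenotypes$path %||% ""))
    stop("phenotype file not found: ", config$phenotypes$path)
  known <- c("filter", "impute", "pheno", "structure", "ld", "gwas",
             "predict")
  bad <- setdiff(config$stages %||% character(0), known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(config)
}
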