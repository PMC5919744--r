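#' Read genotypes from VCF or a delimited dosage matrix
#'
#' VCF input is parsed with \pkg{VariantAnnotation}; only the GT field is
#' used.  Records that are not biallelic SNPs (multi-allelic sites,
#' indels) are dropped with a message reporting the count.  Positions are
#' kept 1-based as in the VCF.  Dosage input is a tab- or
#' comma-delimited individuals x markers table whose first column holds
#' individual ids and whose remaining column names are "chrom:pos"
#' marker keys.
#'
#' @param path file to read.
#' @param format `"vcf"` or `"dosage"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  snp <- n_alt == 1 & nchar(ref) == 1 & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message("dropped ", n_drop, " record(s) that are not biallelic SNPs")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT[snp, , drop = FALSE]
  lut <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
           "1|0" = 1, "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA,
           "." = NA)
  unknown <- setdiff(unique(as.vector(gt)), names(lut))
  if (length(unknown))
    stop("unsupported GT value(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  X <- t(matrix(lut[as.vector(gt)], nrow(gt), ncol(gt)))
  rownames(X) <- colnames(gt)
  map <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[snp],
    pos = GenomicRanges::start(rr)[snp],
    ref = ref[snp], alt = alt1[snp], stringsAsFactors = FALSE)
  geno_matrix(X, map)
}

read_genotypes_dosage <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  X <- as.matrix(dt[, -1, drop = FALSE])
  keys <- colnames(X)
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2)
  if (length(bad))
    stop("dosage column name(s) not of the form 'chrom:pos': ",
         paste(keys[head(bad, 3)], collapse = ", "))
  map <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    stringsAsFactors = FALSE)
  geno_matrix(X, map, ids = ids)
}

#' Write genotypes to VCF or a delimited dosage matrix
#'
#' The VCF writer emits a minimal VCF 4.2 with GT as the only FORMAT
#' field and `./.` for missing calls.
#'
#' @param g a [geno_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"dosage"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  check_geno(g)
  if (format == "dosage") {
    df <- data.frame(id = rownames(g$X), g$X, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(path))
  }
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", ncol(g$X), nrow(g$X))
  ok <- !is.na(t(g$X))
  gt[ok] <- code[t(g$X)[ok] + 1]
  body <- paste(g$map$chrom, g$map$pos,
                paste(g$map$chrom, g$map$pos, sep = ":"),
                g$map$ref, g$map$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##contig=<ID=", unique(g$map$chrom), ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g$X)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read or write a long-format phenotype table
#'
#' Long format has one row per plot: columns `genotype`, `environment`,
#' `replicate`, then one numeric column per trait.
#'
#' @param path delimited text file (tab or comma separated).
#' @return `read_phenotypes`: a data.frame in long format.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("genotype", "environment", "replicate")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns ",
         paste(need, collapse = ", "))
  df$genotype <- as.character(df$genotype)
  df$environment <- as.character(df$environment)
  df
}

#' @rdname read_phenotypes
#' @param tbl data.frame to write.
#' @return `write_phenotypes`: `path`, invisibly.
#' @export
write_phenotypes <- function(tbl, path) {
  data.table::fwrite(tbl, path, sep = "\t", quote = FALSE)
  invisible(path)
}
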