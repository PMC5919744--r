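#' Genotype matrix with marker map
#'
#' The central genotype container: an individuals x markers matrix of
#' additive allele dosages (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing call) together with a marker
#' map giving chromosome, physical position and allele labels.  Markers
#' must be strictly ordered by (chromosome, position) and individual ids
#' must be unique.
#'
#' @param X integer or numeric matrix of dosages in \{0, 1, 2, NA\};
#'   rows are individuals, columns are markers.
#' @param map data.frame with one row per marker and columns `chrom`,
#'   `pos` (1-based bp), and optionally `ref` and `alt` allele labels
#'   (defaulting to "A"/"T" when genotypes come from a dosage file
#'   without allele information).
#' @param ids character vector of individual identifiers; defaults to
#'   `rownames(X)` or `ind1..indN`.
#'
#' @return An object of class `geno_matrix`: a list with elements `X`
#'   (dosage matrix, dimnames set to ids and "chrom:pos" marker names),
#'   and `map`.
#' @export
geno_matrix <- function(X, map, ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(X)))
  ids <- as.character(ids)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(map)))
    stop("marker map must have columns 'chrom' and 'pos'")
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "T"
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(X))
    stop("map has ", nrow(map), " rows but X has ", ncol(X), " columns")
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  key <- paste(map$chrom, map$pos, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in marker map: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    X <- X[, ord, drop = FALSE]
    key <- key[ord]
  }
  bad <- X[!is.na(X) & !(X %in% c(0, 1, 2))]
  if (length(bad))
    stop("dosages must be in {0, 1, 2, NA}; found ",
         paste(unique(bad)[1:min(3, length(unique(bad)))], collapse = ", "))
  rownames(X) <- ids
  colnames(X) <- key
  rownames(map) <- NULL
  structure(list(X = X, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nm <- ncol(x$X)
  miss <- mean(is.na(x$X))
  cat(sprintf(
    "geno_matrix: %d individuals x %d markers on %d chromosome(s), %.1f%% missing\n",
    nrow(x$X), nm, length(unique(x$map$chrom)), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$X)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i individual index (row) selector.
#' @param j marker index (column) selector.
#' @param ... ignored.
#' @return A `geno_matrix` restricted to the selected individuals/markers.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  geno_matrix(x$X[i, j, drop = FALSE], x$map[j, , drop = FALSE],
              ids = rownames(x$X)[i])
}

#' Individual identifiers of a genotype matrix
#' @param g a [geno_matrix()].
#' @return Character vector of individual ids.
#' @export
geno_ids <- function(g) rownames(g$X)

# internal: check the object and optionally completeness
check_geno <- function(g, complete = FALSE, what = "genotype matrix") {
  if (!inherits(g, "geno_matrix")) stop(what, " must be a geno_matrix")
  if (complete && anyNA(g$X))
    stop(what, " must be complete (no missing dosages); impute first")
  invisible(g)
}
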