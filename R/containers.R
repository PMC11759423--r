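#' Genotype matrix container
#'
#' Holds an individuals-by-SNP allele dosage matrix (0/1/2, `NA` allowed)
#' together with the marker map (chromosome, physical and genetic position)
#' and, optionally, the phased haplotypes the dosages were formed from.
#'
#' @param dosages numeric matrix, individuals in rows (rownames are genotype
#'   IDs), SNPs in columns (colnames are SNP IDs).
#' @param map data.frame with columns `snp`, `chrom`, `pos_bp`, `pos_cM` and
#'   optionally `ref`, `alt`; one row per column of `dosages`, same order.
#' @param haplotypes optional list of two 0/1 matrices (`h1`, `h2`) with the
#'   same dimnames as `dosages`; their sum must equal `dosages`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map, haplotypes = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    stop("dosage matrix must have individual IDs as rownames")
  if (nrow(map) != ncol(dosages))
    stop("map must describe every SNP column")
  req <- c("snp", "chrom", "pos_bp")
  if (!all(req %in% names(map)))
    stop("map must contain columns: ", paste(req, collapse = ", "))
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad) && any(abs(bad - round(bad)) > 0 & (bad < 0 | bad > 2)))
    stop("dosages must lie in [0, 2]")
  if (!is.null(haplotypes)) {
    stopifnot(is.list(haplotypes), length(haplotypes) == 2L)
    names(haplotypes) <- c("h1", "h2")
  }
  structure(list(dosages = dosages, map = map, haplotypes = haplotypes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs on %d chromosome(s)%s\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$map$chrom)),
              if (!is.null(x$haplotypes)) ", phased" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

is_phased <- function(x) !is.null(x$haplotypes)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param x a [genotype_matrix()].
#' @param individuals,snps character IDs or index vectors; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  i <- if (is.null(individuals)) seq_len(nrow(x$dosages)) else individuals
  j <- if (is.null(snps)) seq_len(ncol(x$dosages)) else snps
  if (is.character(j)) j <- match(j, colnames(x$dosages))
  hap <- x$haplotypes
  if (!is.null(hap)) hap <- lapply(hap, function(h) h[i, j, drop = FALSE])
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  x$map[j, , drop = FALSE], hap)
}

#' Relationship kernel container
#'
#' A symmetric relationship matrix (genomic G or phenomic H) with aligned
#' individual IDs and a source tag.
#'
#' @param mat symmetric numeric matrix with identical row/column names.
#' @param source character tag, e.g. `"G"` or `"H_d1_raw"`.
#' @param tol symmetry tolerance.
#' @return an object of class `kernel_matrix` (a matrix with attributes).
#' @export
kernel_matrix <- function(mat, source = "K", tol = 1e-10) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("kernel must be square")
  if (is.null(rownames(mat))) stop("kernel must carry individual IDs")
  if (anyDuplicated(rownames(mat))) stop("kernel IDs must be unique")
  if (max(abs(mat - t(mat))) > tol) stop("kernel must be symmetric")
  if (any(!is.finite(diag(mat)))) stop("kernel diagonal must be finite")
  mat <- (mat + t(mat)) / 2
  colnames(mat) <- rownames(mat)
  structure(mat, class = c("kernel_matrix", "matrix"), source = source)
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix '%s'> %d x %d, diag mean %.3f\n",
              attr(x, "source"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

kernel_ids <- function(k) rownames(k)

#' Spectra matrix container
#'
#' Individual-by-wavelength reflectance values with a provenance tag
#' recording which pre-processing produced them.
#'
#' @param values numeric matrix, individuals in rows (rownames are IDs),
#'   wavelengths in columns.
#' @param wavelengths strictly increasing numeric grid in nm.
#' @param provenance one of `"raw"`, `"normalized"`, `"detrended"`,
#'   `"d1_raw"`, `"d1_norm"`, `"d2_raw"`, `"d2_norm"`.
#' @return an object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(values, wavelengths, provenance = "raw") {
  values <- as.matrix(values)
  if (length(wavelengths) != ncol(values))
    stop("one wavelength per column required")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(rownames(values))) stop("spectra must carry individual IDs")
  colnames(values) <- format(wavelengths, trim = TRUE, digits = 12)
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 provenance = provenance),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix '%s'> %d individuals x %d wavelengths (%.0f-%.0f nm)\n",
              x$provenance, nrow(x$values), ncol(x$values),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

# Pearson correlation guarded for degenerate inputs; NA (flagged) when either
# vector is constant, error below 3 pairs.
guarded_cor <- function(x, y, min_pairs = 3L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_pairs)
    stop("need at least ", min_pairs, " paired values, got ", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(x, y)
}
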