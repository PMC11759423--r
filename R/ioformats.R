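#' Write genotypes to a minimal VCF
#'
#' VCFv4.2 with GT field only; 1-based positions, chromosome labels as in
#' the map; REF/ALT from the map when present (defaults A/C). Dosages are
#' rounded to the nearest integer for genotype encoding; `NA` becomes
#' `./.`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  map <- genotypes$map
  D <- round(t(genotypes$dosages)) # variants x samples
  gt <- matrix(c("0/0", "0/1", "1/1")[D + 1], nrow(D), ncol(D))
  gt[is.na(D)] <- "./."
  ref <- map$ref %||% rep("A", nrow(map))
  alt <- map$alt %||% rep("C", nrow(map))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(genotypes$dosages)),
                 collapse = "\t"))
  body <- cbind(map$chrom, map$pos_bp, map$snp, ref, alt, ".", ".", ".",
                "GT", gt)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read genotypes from VCF or PLINK-style transposed text
#'
#' VCF parsing honours the GT field; multiallelic or non-SNP sites are
#' rejected and counted (attribute `"rejected"`); missing GT becomes a
#' missing dosage.
#'
#' @param path input file.
#' @param format `"vcf"` or `"plink"` (transposed text as written by
#'   [write_plink_t()]).
#' @return a [genotype_matrix()] (map includes `ref`/`alt` for VCF input).
#' @export
read_genotypes <- function(path, format = c("vcf", "plink")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plink") return(read_plink_t(path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1 & fix$ALT != "."
  n_rejected <- sum(!biallelic)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dos <- t(apply(gt, 2, function(col) vapply(col, count_alt, 0)))
  # apply over columns returns samples x variants after t(); guard 1-sample
  if (nrow(fix) == 1) dos <- matrix(dos, ncol = 1,
                                    dimnames = list(colnames(gt), NULL))
  map <- data.frame(snp = ifelse(is.na(fix$ID) | fix$ID == ".",
                                 paste0(fix$CHROM, "_", fix$POS), fix$ID),
                    chrom = fix$CHROM, pos_bp = as.integer(fix$POS),
                    pos_cM = NA_real_, ref = fix$REF, alt = fix$ALT)
  colnames(dos) <- map$snp
  out <- genotype_matrix(dos, map)
  attr(out, "rejected") <- n_rejected
  out
}

#' Write genotypes as PLINK-style transposed text
#'
#' Tab-separated: columns `snp`, `chrom`, `pos_bp`, `pos_cM`, then one
#' dosage column per individual.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_plink_t <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- cbind(genotypes$map[, c("snp", "chrom", "pos_bp", "pos_cM")],
              as.data.frame(t(genotypes$dosages)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_plink_t <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  meta <- c("snp", "chrom", "pos_bp", "pos_cM")
  if (!all(meta %in% names(df)))
    stop("PLINK-style text must carry columns ",
         paste(meta, collapse = ", "))
  dos <- t(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]))
  colnames(dos) <- df$snp
  map <- df[, meta]
  map$chrom <- as.character(map$chrom)
  genotype_matrix(dos, map)
}

#' Write / read long-format phenotype records
#'
#' CSV with columns `genotype_id`, `family`, `location`, `year`,
#' `environment`, `tree_id`, `tree_age`, `trait`, `value`. On reading,
#' `environment` is derived as `location_year` when absent; duplicate
#' tree-by-trait-by-environment rows are an error.
#'
#' @param records phenotype records data.frame.
#' @param path file path.
#' @return `write_phenotypes`: invisibly `path`; `read_phenotypes`: the
#'   records data.frame.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty phenotype file: ", path)
  req <- c("genotype_id", "trait", "value")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!"environment" %in% names(d)) {
    if (!all(c("location", "year") %in% names(d)))
      stop("missing required column(s): environment (or location + year)")
    d$environment <- paste(d$location, d$year, sep = "_")
  }
  if (!"tree_id" %in% names(d))
    d$tree_id <- paste(d$genotype_id, d$environment, sep = ".")
  key <- paste(d$tree_id, d$trait, d$environment)
  if (anyDuplicated(key))
    stop("duplicate tree x trait x environment rows in ", path)
  d
}

#' Write / read spectra as CSV
#'
#' First column `genotype_id`, remaining columns the wavelengths in nm.
#'
#' @param spectra a [spectra_matrix()].
#' @param path file path.
#' @param provenance provenance tag to attach on reading.
#' @return `write_spectra`: invisibly `path`; `read_spectra`: a
#'   `spectra_matrix`.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  df <- data.frame(genotype_id = rownames(spectra$values),
                   spectra$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, provenance = "raw") {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "genotype_id") stop("first column must be genotype_id")
  vals <- as.matrix(d[, -1, drop = FALSE])
  rownames(vals) <- d$genotype_id
  spectra_matrix(vals, as.numeric(colnames(vals)), provenance = provenance)
}

#' Write / read a relationship kernel as TSV
#'
#' Square tab-separated matrix with a header row and first column of IDs.
#'
#' @param kernel a [kernel_matrix()].
#' @param path file path.
#' @param source source tag to attach on reading.
#' @return `write_kernel`: invisibly `path`; `read_kernel`: a
#'   `kernel_matrix`.
#' @export
write_kernel <- function(kernel, path) {
  df <- data.frame(id = rownames(kernel), unclass(kernel),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path, source = "K") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  kernel_matrix(m, source = source)
}

#' Write clonal values as TSV
#'
#' @param values named numeric vector (or list per trait) of BLUPs.
#' @param trait trait label (ignored when `values` is a named list).
#' @param path file path.
#' @return invisibly `path`.
#' @export
write_clonal_values <- function(values, path, trait = "trait") {
  if (!is.list(values)) values <- stats::setNames(list(values), trait)
  df <- do.call(rbind, lapply(names(values), function(tr)
    data.frame(genotype_id = names(values[[tr]]), trait = tr,
               blup = unname(values[[tr]]))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
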