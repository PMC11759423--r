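#' Variant table container
#'
#' Per-variant metadata plus per-sample dosages and (optionally) read
#' depths, the substrate for hard filtering and dataset concordance.
#'
#' @param info data.frame with columns `snp`, `chrom`, `pos`, `type`
#'   (`"SNP"`, `"indel"` or `"multiallelic"`) and optionally `ref`, `alt`.
#' @param dosages samples x variants matrix (0/1/2, `NA` = missing call).
#' @param depth optional samples x variants read-depth matrix (>= 0).
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(info, dosages, depth = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(info) != ncol(dosages))
    stop("info must describe every dosage column")
  if (!all(c("snp", "chrom", "pos") %in% names(info)))
    stop("info needs columns snp, chrom, pos")
  if (is.null(info$type)) info$type <- "SNP"
  if (is.null(rownames(dosages)))
    stop("dosage matrix must carry sample IDs as rownames")
  colnames(dosages) <- info$snp
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(dosages)))
      stop("depth must match dosage dimensions")
    if (any(depth < 0, na.rm = TRUE)) stop("depths must be >= 0")
    dimnames(depth) <- dimnames(dosages)
  }
  structure(list(info = info, dosages = dosages, depth = depth),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d samples x %d variants (%d SNPs)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$info$type == "SNP")))
  invisible(x)
}

#' Hard-filter a variant table
#'
#' Applies, in order: genotype-level depth masking, variant mean-depth
#' filter, removal of indels and multiallelic variants, minor-allele
#' frequency filter, chromosome filter, variant missingness filter and
#' sample missingness filter. Counts removed per rule are reported.
#'
#' @param vt a [variant_table()].
#' @param min_genotype_depth calls below this depth are set missing.
#' @param min_mean_depth variants with lower mean depth (over all samples)
#'   are removed.
#' @param min_maf variants with minor allele frequency below this are
#'   removed.
#' @param max_variant_missing variants with missing call rate exceeding
#'   this are removed.
#' @param max_sample_missing samples with missing call rate exceeding this
#'   are removed.
#' @param chromosomes retained chromosome labels (default `"1"..."17"`).
#' @return the filtered `variant_table`; attribute `"report"` is a
#'   data.frame of per-rule removal counts.
#' @export
filter_variants <- function(vt, min_genotype_depth = 4, min_mean_depth = 4,
                            min_maf = 0.01, max_variant_missing = 0.7,
                            max_sample_missing = 0.7,
                            chromosomes = as.character(1:17)) {
  stopifnot(inherits(vt, "variant_table"))
  dos <- vt$dosages
  info <- vt$info
  report <- data.frame(rule = character(0), removed = integer(0))
  note <- function(rule, removed)
    rbind(report, data.frame(rule = rule, removed = removed))
  masked <- 0L
  if (!is.null(vt$depth) && min_genotype_depth > 0) {
    low <- vt$depth < min_genotype_depth & !is.na(dos)
    masked <- sum(low)
    dos[low] <- NA
  }
  report <- note("genotype_depth_masked", masked)
  keep <- rep(TRUE, ncol(dos))
  if (!is.null(vt$depth) && min_mean_depth > 0) {
    md <- colMeans(vt$depth)
    drop_md <- keep & md < min_mean_depth
    report <- note("variant_mean_depth", sum(drop_md))
    keep <- keep & !drop_md
  } else report <- note("variant_mean_depth", 0L)
  drop_type <- keep & info$type != "SNP"
  report <- note("indel_or_multiallelic", sum(drop_type))
  keep <- keep & !drop_type
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- keep & (is.na(maf) | maf < min_maf)
  report <- note("maf", sum(drop_maf))
  keep <- keep & !drop_maf
  drop_chr <- keep & !(as.character(info$chrom) %in% chromosomes)
  report <- note("chromosome", sum(drop_chr))
  keep <- keep & !drop_chr
  vmiss <- colMeans(is.na(dos))
  drop_miss <- keep & vmiss > max_variant_missing
  report <- note("variant_missingness", sum(drop_miss))
  keep <- keep & !drop_miss
  dos <- dos[, keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  smiss <- rowMeans(is.na(dos))
  keep_s <- smiss <= max_sample_missing
  report <- note("sample_missingness", sum(!keep_s))
  dos <- dos[keep_s, , drop = FALSE]
  depth <- vt$depth
  if (!is.null(depth)) depth <- depth[keep_s, keep, drop = FALSE]
  out <- variant_table(info, dos, depth)
  attr(out, "report") <- report
  attr(out, "removed_samples") <- rownames(vt$dosages)[!keep_s]
  out
}

is_strand_ambiguous <- function(ref, alt) {
  paste0(ref, alt) %in% c("AT", "TA", "CG", "GC")
}

#' Positional overlap and allele harmonization of two genotype datasets
#'
#' Intersects variants by (chromosome, position). Matching ref/alt pairs
#' are kept as-is; swapped pairs are kept with dataset-B dosages flipped
#' (`2 - d`); strand-ambiguous (A/T, C/G) or inconsistent allele pairs are
#' dropped. Positions duplicated within a dataset are dropped with a
#' warning.
#'
#' @param a,b [variant_table()] objects (or anything with `$info` carrying
#'   `chrom`, `pos` and optionally `ref`/`alt`).
#' @return list with `keys` (data.frame of shared variants and the action
#'   taken), `dosages_b` (B's dosages over shared variants, flips applied)
#'   and a `report` of counts.
#' @export
overlap_by_position <- function(a, b) {
  key_of <- function(vt) paste(vt$info$chrom, vt$info$pos, sep = ":")
  ka <- key_of(a); kb <- key_of(b)
  dup_a <- ka %in% ka[duplicated(ka)]
  dup_b <- kb %in% kb[duplicated(kb)]
  if (any(dup_a) || any(dup_b))
    warning(sum(dup_a) + sum(dup_b),
            " variant(s) at duplicated positions dropped")
  shared <- intersect(ka[!dup_a], kb[!dup_b])
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  has_alleles <- !is.null(a$info$ref) && !is.null(b$info$ref)
  action <- rep("match", length(shared))
  if (has_alleles) {
    ra <- a$info$ref[ia]; aa <- a$info$alt[ia]
    rb <- b$info$ref[ib]; ab <- b$info$alt[ib]
    swapped <- ra == ab & aa == rb & ra != rb
    same <- ra == rb & aa == ab
    ambig <- is_strand_ambiguous(ra, aa) | is_strand_ambiguous(rb, ab)
    action[swapped & !ambig] <- "flip"
    action[!(same | swapped) | ambig] <- "drop"
  }
  keep <- action != "drop"
  keys <- data.frame(chrom = a$info$chrom[ia], pos = a$info$pos[ia],
                     snp_a = a$info$snp[ia], snp_b = b$info$snp[ib],
                     action = action)[keep, , drop = FALSE]
  dos_b <- b$dosages[, ib[keep], drop = FALSE]
  flip <- keys$action == "flip"
  if (any(flip)) dos_b[, flip] <- 2 - dos_b[, flip]
  list(keys = keys, dosages_b = dos_b,
       report = data.frame(shared = length(shared),
                           kept = sum(keep),
                           flipped = sum(action == "flip"),
                           dropped = sum(action == "drop"),
                           duplicated = sum(dup_a) + sum(dup_b)))
}

#' Non-reference discordance between two dosage sets
#'
#' `NRD = mismatches / (mismatches + heterozygous matches + homozygous
#' alternative matches)`: homozygous-reference matches are excluded from
#' the denominator. Missing entries are excluded pairwise. With a matrix
#' input the metric is computed per sample (row) and averaged.
#'
#' @param truth,test numeric dosage vectors or samples x variants matrices
#'   with aligned dimensions.
#' @return list with `per_sample` (named vector, `NA` when the denominator
#'   is zero) and `mean` (over defined samples).
#' @export
non_reference_discordance <- function(truth, test) {
  if (is.null(dim(truth))) truth <- matrix(truth, nrow = 1)
  if (is.null(dim(test))) test <- matrix(test, nrow = 1)
  if (!identical(dim(truth), dim(test)))
    stop("truth and test must have identical dimensions")
  per <- vapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]; s <- test[i, ]
    ok <- !is.na(t) & !is.na(s)
    t <- t[ok]; s <- s[ok]
    mm <- sum(t != s)
    het <- sum(t == s & t == 1)
    hom <- sum(t == s & t == 2)
    den <- mm + het + hom
    if (den == 0) NA_real_ else mm / den
  }, 0)
  names(per) <- rownames(truth)
  list(per_sample = per, mean = mean(per, na.rm = TRUE))
}

#' Squared Pearson correlation between dosage sets
#'
#' Per-sample squared correlation between two aligned dosage vectors;
#' constant vectors yield a flagged `NA`. Missing entries are excluded
#' pairwise.
#'
#' @inheritParams non_reference_discordance
#' @return list with `per_sample` and `mean`.
#' @export
dosage_r2 <- function(truth, test) {
  if (is.null(dim(truth))) truth <- matrix(truth, nrow = 1)
  if (is.null(dim(test))) test <- matrix(test, nrow = 1)
  if (!identical(dim(truth), dim(test)))
    stop("truth and test must have identical dimensions")
  per <- vapply(seq_len(nrow(truth)), function(i) {
    r <- tryCatch(guarded_cor(truth[i, ], test[i, ]),
                  error = function(e) NA_real_)
    as.numeric(r)^2
  }, 0)
  names(per) <- rownames(truth)
  list(per_sample = per, mean = mean(per, na.rm = TRUE))
}

#' Random SNP subsets for downsampling experiments
#'
#' @param snp_ids character vector of SNP IDs.
#' @param subset_size SNPs per subset (without replacement).
#' @param reps number of subsets.
#' @param seed integer seed.
#' @return list of `reps` character vectors.
#' @export
random_snp_subsets <- function(snp_ids, subset_size, reps = 20, seed = NULL) {
  if (subset_size > length(snp_ids))
    stop("subset_size exceeds the number of SNPs")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(reps), function(i) sample(snp_ids, subset_size))
}
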