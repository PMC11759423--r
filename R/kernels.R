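#' Genomic relationship matrix (VanRaden)
#'
#' Centers each SNP column by twice its sample allele frequency, scales by
#' `sqrt(2 p (1 - p))`, and returns the cross-product divided by the number
#' of retained SNPs. Monomorphic SNPs are dropped; missing dosages are
#' filled with the per-SNP mean before centering.
#'
#' @param genotypes a [genotype_matrix()].
#' @return a [kernel_matrix()] with source tag `"G"`.
#' @export
compute_grm <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosages
  if (nrow(D) < 2) stop("need >= 2 individuals")
  if (anyNA(D)) {
    fill <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- fill[idx[, 2]]
  }
  p <- colMeans(D) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(D, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  kernel_matrix(tcrossprod(W) / ncol(W), source = "G")
}

#' Column-wise autoscaling of spectra
#'
#' Centers and scales each wavelength across individuals to mean zero and
#' unit sample standard deviation; zero-variance columns are set to zero.
#' (Distinct from the row-wise standard normal variate used inside
#' [detrend_spectra()].)
#'
#' @param spectra a [spectra_matrix()].
#' @param by `"column"` (default, per wavelength) or `"row"` (per spectrum).
#' @return a `spectra_matrix` with provenance `"normalized"`.
#' @export
normalize_spectra <- function(spectra, by = c("column", "row")) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  by <- match.arg(by)
  X <- spectra$values
  if (by == "column") {
    if (nrow(X) < 2) stop("need >= 2 individuals for column scaling")
    Z <- scale(X)
    Z[, attr(Z, "scaled:scale") == 0] <- 0
  } else {
    Z <- t(apply(X, 1, function(r) {
      s <- stats::sd(r)
      if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
  }
  Z <- matrix(as.numeric(Z), nrow(X), ncol(X), dimnames = dimnames(X))
  spectra_matrix(Z, spectra$wavelengths, provenance = "normalized")
}

#' Detrend spectra: SNV followed by quadratic baseline removal
#'
#' Applies the standard normal variate transformation per spectrum (row
#' centered and divided by the row sample standard deviation) and then
#' subtracts the least-squares quadratic in wavelength, returning the
#' residuals.
#'
#' @param spectra a [spectra_matrix()].
#' @return a `spectra_matrix` with provenance `"detrended"`.
#' @export
detrend_spectra <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  X <- spectra$values
  if (ncol(X) < 3) stop("need >= 3 wavelengths for a quadratic fit")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0))
    stop("constant spectrum for individual(s): ",
         paste(rownames(X)[sds == 0], collapse = ", "))
  Z <- (X - rowMeans(X)) / sds
  wl <- spectra$wavelengths
  # standardized wavelength keeps the normal equations well conditioned;
  # the projection spans the same quadratic space
  ws <- (wl - mean(wl)) / stats::sd(wl)
  Q <- cbind(1, ws, ws^2)
  # residual-maker applied to every row at once
  P <- Q %*% solve(crossprod(Q), t(Q))
  R <- Z - Z %*% P
  dimnames(R) <- dimnames(X)
  spectra_matrix(R, wl, provenance = "detrended")
}

#' Savitzky-Golay derivative of spectra
#'
#' Per-spectrum Savitzky-Golay convolution along the wavelength axis.
#' Output length equals input length: edge windows use the polynomial
#' fitted to the first/last full window. The derivative is per index step
#' of the (uniform) wavelength grid.
#'
#' @param spectra a [spectra_matrix()].
#' @param deriv_order derivative order (1 or 2).
#' @param filter_order polynomial order of the filter.
#' @param filter_length window length; must be odd and exceed
#'   `filter_order`.
#' @return a `spectra_matrix` with provenance `"d1_*"` or `"d2_*"`.
#' @export
savgol_derivative <- function(spectra, deriv_order, filter_order,
                              filter_length) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (filter_length %% 2 == 0) stop("filter_length must be odd")
  if (filter_length <= filter_order)
    stop("filter_length must exceed filter_order")
  X <- spectra$values
  if (ncol(X) < filter_length)
    stop("need at least filter_length wavelengths")
  out <- t(apply(X, 1, signal::sgolayfilt, p = filter_order,
                 n = filter_length, m = deriv_order))
  dimnames(out) <- dimnames(X)
  src <- sub("^(normalized)$", "norm", spectra$provenance)
  spectra_matrix(out, spectra$wavelengths,
                 provenance = sprintf("d%d_%s", deriv_order, src))
}

#' The seven raw and pre-processed spectra matrices
#'
#' Returns raw, normalized, detrended, and first/second Savitzky-Golay
#' derivatives of the raw and normalized spectra (first derivative: filter
#' order 2, length 37; second derivative: order 3, length 61). Every matrix
#' keeps the full variable count.
#'
#' @param spectra_raw a raw [spectra_matrix()].
#' @return named list of seven `spectra_matrix` objects: `raw`,
#'   `normalized`, `detrended`, `d1_raw`, `d1_norm`, `d2_raw`, `d2_norm`.
#' @export
preprocess_suite <- function(spectra_raw) {
  stopifnot(inherits(spectra_raw, "spectra_matrix"))
  norm <- normalize_spectra(spectra_raw)
  list(raw = spectra_raw,
       normalized = norm,
       detrended = detrend_spectra(spectra_raw),
       d1_raw = savgol_derivative(spectra_raw, 1, 2, 37),
       d1_norm = savgol_derivative(norm, 1, 2, 37),
       d2_raw = savgol_derivative(spectra_raw, 2, 3, 61),
       d2_norm = savgol_derivative(norm, 2, 3, 61))
}

#' Phenomic relationship matrix from spectra
#'
#' Same construction as [compute_grm()] applied to spectral variables:
#' columns centered and scaled to unit sample standard deviation,
#' cross-product divided by the number of variables. Zero-variance columns
#' are dropped.
#'
#' @param spectra a [spectra_matrix()].
#' @return a [kernel_matrix()] with source tag `"H_<provenance>"`.
#' @export
compute_phenomic_kernel <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  X <- spectra$values
  if (nrow(X) < 2) stop("need >= 2 individuals")
  Z <- scale(X)
  keep <- attr(Z, "scaled:scale") > 0
  if (!any(keep)) stop("all spectral columns are degenerate")
  Z <- Z[, keep, drop = FALSE]
  kernel_matrix(tcrossprod(Z) / ncol(Z),
                source = paste0("H_", spectra$provenance))
}
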