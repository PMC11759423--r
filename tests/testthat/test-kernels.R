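# brute-force VanRaden GRM: explicit double loop
grm_bruteforce <- function(D) {
  p <- colMeans(D) / 2
  keep <- p > 0 & p < 1
  D <- D[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(D); m <- ncol(D)
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (k in 1:m)
      s <- s + (D[i, k] - 2 * p[k]) * (D[j, k] - 2 * p[k]) /
        (2 * p[k] * (1 - p[k]))
    G[i, j] <- s / m
  }
  G
}

test_that("the GRM matches the hand-computed toy and the brute-force oracle", {
  g <- genotype_matrix(
    matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
    data.frame(snp = c("s1", "s2"), chrom = "1", pos_bp = c(1, 2),
               pos_cM = c(0, 1)))
  G <- compute_grm(g)
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
  set.seed(3)
  for (i in 1:3) {
    n <- sample(4:10, 1); m <- sample(5:10, 1)
    D <- matrix(rbinom(n * m, 2, runif(1, 0.2, 0.5)), n, m,
                dimnames = list(paste0("i", 1:n), paste0("s", 1:m)))
    if (all(colMeans(D) %in% c(0, 2))) next
    gm <- genotype_matrix(D, data.frame(snp = colnames(D), chrom = "1",
                                        pos_bp = 1:m, pos_cM = 1:m))
    expect_equal(unclass(compute_grm(gm)), grm_bruteforce(D),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("GRM handles monomorphic, duplicated and missing input correctly", {
  mono <- genotype_matrix(
    matrix(2, 3, 2, dimnames = list(letters[1:3], c("s1", "s2"))),
    data.frame(snp = c("s1", "s2"), chrom = "1", pos_bp = 1:2, pos_cM = 1:2))
  expect_error(compute_grm(mono), "polymorphic")

  g <- toy_genotypes(n = 8, m = 12, seed = 4)
  G1 <- compute_grm(g)
  dup <- genotype_matrix(cbind(g$dosages, g$dosages),
                         rbind(g$map, transform(g$map,
                                                snp = paste0(snp, "b"))))
  expect_equal(unclass(compute_grm(dup)), unclass(G1), tolerance = 1e-12)

  miss <- g
  miss$dosages[1, 1] <- NA
  expect_silent(compute_grm(miss))
})

test_that("kernels are symmetric and positive semi-definite", {
  g <- toy_genotypes(n = 15, m = 60, seed = 6)
  G <- compute_grm(g)
  expect_lt(max(abs(unclass(G) - t(unclass(G)))), 1e-10)
  expect_gt(min(eigen(unclass(G), symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
  sp <- toy_spectra(n = 12, n_wl = 80, seed = 7)
  H <- compute_phenomic_kernel(sp)
  expect_gt(min(eigen(unclass(H), symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
})

test_that("column normalization autoscales and zeroes degenerate wavelengths", {
  wl <- c(1100, 1200, 1300)
  sp <- spectra_matrix(matrix(c(1, 2, 3, 5, 5, 5, 0, 1, 4), 3, 3,
                              dimnames = list(c("a", "b", "c"), NULL)), wl)
  nm <- normalize_spectra(sp)
  expect_equal(nm$values[, 1], c(a = -1, b = 0, c = 1))
  expect_equal(unname(nm$values[, 2]), c(0, 0, 0)) # constant column rule
  expect_equal(mean(nm$values[, 3]), 0)
  expect_equal(sd(nm$values[, 3]), 1)
  expect_equal(nm$provenance, "normalized")
})

test_that("detrending annihilates quadratic spectra and standardizes rows", {
  n_wl <- 50
  wl <- seq(1050, 2500, length.out = n_wl)
  quad <- outer(c(1, 2, -1), wl^2) + outer(c(0, 3, 1), wl) + 5
  rownames(quad) <- c("a", "b", "c")
  sp <- spectra_matrix(quad, wl)
  dt <- detrend_spectra(sp)
  expect_lt(max(abs(dt$values)), 1e-10)

  # SNV inside detrending: row (1,2,3) standardizes to (-1,0,1)
  x <- c(1, 2, 3)
  expect_equal((x - mean(x)) / sd(x), c(-1, 0, 1))

  flat <- spectra_matrix(matrix(2, 2, n_wl,
                                dimnames = list(c("a", "b"), NULL)), wl)
  expect_error(detrend_spectra(flat), "constant spectrum.*a")
})

test_that("Savitzky-Golay derivatives equal polynomial derivatives everywhere", {
  n_wl <- 120
  wl <- seq(1050, 2500, length.out = n_wl)
  b <- 0.37
  lin <- matrix(b * seq_len(n_wl), 1, dimnames = list("a", NULL))
  sp <- spectra_matrix(lin, wl)
  d1 <- savgol_derivative(sp, 1, 2, 37)
  expect_equal(unname(d1$values[1, ]), rep(b, n_wl), tolerance = 1e-8)
  expect_equal(ncol(d1$values), n_wl)

  a <- 0.05
  quad <- matrix(a * seq_len(n_wl)^2, 1, dimnames = list("a", NULL))
  d2 <- savgol_derivative(spectra_matrix(quad, wl), 2, 3, 61)
  interior <- 31:(n_wl - 30)
  expect_equal(unname(d2$values[1, interior]), rep(2 * a, length(interior)),
               tolerance = 1e-8)

  const <- spectra_matrix(matrix(4, 1, n_wl, dimnames = list("a", NULL)), wl)
  expect_equal(max(abs(savgol_derivative(const, 1, 2, 37)$values)), 0,
               tolerance = 1e-10)
  expect_error(savgol_derivative(sp, 1, 2, 36), "odd")
})

test_that("the pre-processing suite returns seven full-width matrices", {
  sp <- toy_spectra(n = 5, n_wl = 120, seed = 8)
  suite <- preprocess_suite(sp)
  expect_length(suite, 7)
  expect_named(suite, c("raw", "normalized", "detrended", "d1_raw",
                        "d1_norm", "d2_raw", "d2_norm"))
  expect_identical(suite$raw$values, sp$values)
  for (s in suite) expect_equal(ncol(s$values), 120)
})

test_that("the phenomic kernel follows the autoscaled cross-product construction", {
  wl <- c(1100, 1200)
  sp <- spectra_matrix(matrix(c(0, 2, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), NULL)), wl)
  H <- compute_phenomic_kernel(sp)
  # column autoscale (sample SD) then cross-product / m: diagonal 0.5,
  # off-diagonal -0.5 (off-diagonal = -diagonal for two individuals)
  expect_equal(unclass(H),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
  # individuals with identical spectra: off-diagonal equals the diagonal
  same <- spectra_matrix(rbind(a = c(1, 2, 5, 3), b = c(1, 2, 5, 3),
                               c = c(0, 4, 1, 2)),
                         c(1100, 1200, 1300, 1400))
  Hs <- compute_phenomic_kernel(same)
  expect_equal(Hs["a", "b"], Hs["a", "a"])
  # standardized inputs: diagonal mean near 1 at large m
  sp2 <- toy_spectra(n = 30, n_wl = 500, seed = 9)
  H2 <- compute_phenomic_kernel(sp2)
  expect_lt(abs(mean(diag(H2)) - 1), 0.05)
})
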