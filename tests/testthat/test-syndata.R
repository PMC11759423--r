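test_that("founder allele frequencies follow the configured MAF and are reproducible", {
  cfg <- sim_config(n_founders = 1000, n_families = 0, n_chromosomes = 1,
                    snps_per_chromosome = 1, maf_range = c(0.5, 0.5),
                    seed = 101)
  f <- simulate_founders(cfg)
  freq <- mean(f$dosages) / 2
  expect_lt(abs(freq - 0.5), 0.05)
  f2 <- simulate_founders(cfg)
  expect_identical(f$dosages, f2$dosages)
  expect_identical(f$haplotypes, f2$haplotypes)
})

test_that("monomorphic and invalid configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0)), "monomorphic")
  expect_error(sim_config(var_g = -1), "variances")
  expect_error(sim_config(n_founders = 1), "positive")
  expect_error(sim_config(genetic_signal_fraction = 1.5), "\\[0, 1\\]")
})

test_that("gamete formation is Mendelian and respects the genetic map", {
  map <- data.frame(snp = c("a", "b"), chrom = "1", pos_bp = c(1, 2),
                    pos_cM = c(0, 0))
  # forced heterozygosity: 0/0 x 2/2 parents
  h0 <- matrix(0L, 2, 2, dimnames = list(c("p1", "p2"), map$snp))
  h1 <- h0; h1["p2", ] <- 1L
  h2 <- h0; h2["p2", ] <- 1L
  parents <- genotype_matrix(h1 + h2, map, haplotypes = list(h1, h2))
  kids <- simulate_family(parents, "p1", "p2", 50, seed = 1)
  expect_true(all(kids$dosages == 1))

  # zero recombination between SNPs 0 cM apart
  set.seed(2)
  hA <- matrix(c(1L, 1L, 0L, 0L), 2, 2, dimnames = list(c("p1", "p2"), map$snp))
  hB <- matrix(c(0L, 0L, 1L, 1L), 2, 2, dimnames = list(c("p1", "p2"), map$snp))
  # p1 haplotypes: (1,0) and (0,1) -> any recombinant gamete mixes them
  par2 <- genotype_matrix(hA + hB, map, haplotypes = list(hA, hB))
  kids2 <- simulate_family(par2, "p1", "p1", 200, seed = 3)
  gam <- kids2$haplotypes$h1
  expect_true(all(gam[, 1] != gam[, 2])) # parental configurations only
})

test_that("recombinant fraction at 100 cM matches the Haldane closed form", {
  map <- data.frame(snp = c("a", "b"), chrom = "1", pos_bp = c(1, 2),
                    pos_cM = c(0, 100))
  hA <- matrix(c(1L, 1L, 0L, 0L), 2, 2, dimnames = list(c("p1", "p2"), map$snp))
  hB <- matrix(c(0L, 0L, 1L, 1L), 2, 2, dimnames = list(c("p1", "p2"), map$snp))
  par <- genotype_matrix(hA + hB, map, haplotypes = list(hA, hB))
  kids <- simulate_family(par, "p1", "p1", 2000, seed = 5)
  gams <- rbind(kids$haplotypes$h1, kids$haplotypes$h2)
  rec_frac <- mean(gams[, 1] == gams[, 2]) # parental: (1,0)/(0,1)
  expect_lt(abs(rec_frac - (1 - exp(-2)) / 2), 0.03)
})

test_that("progeny dosages are consistent with parental haplotypes", {
  bundle <- small_population(seed = 21)
  fam <- names(bundle$family_map)[bundle$family_map == "F01"]
  pars <- bundle$pedigree[[fam[1]]]
  hap <- bundle$genotypes$haplotypes
  # every transmitted allele must exist in the corresponding parent
  for (id in fam) {
    for (p in 1:2) {
      gam <- hap[[p]][id, ]
      ok <- gam == hap$h1[pars[p], ] | gam == hap$h2[pars[p], ]
      expect_true(all(ok))
    }
  }
  expect_identical(unname(bundle$genotypes$dosages[fam[1], ]),
                   unname(hap$h1[fam[1], ] + hap$h2[fam[1], ]))
})

test_that("trait records have the configured structure and are reproducible", {
  cfg <- sim_config(n_founders = 30, n_families = 2, progeny_per_family = 5,
                    n_chromosomes = 2, snps_per_chromosome = 20,
                    n_traits = 1, n_environments = 3,
                    replicates_per_genotype = 2, seed = 31)
  b <- simulate_population(cfg)
  r1 <- simulate_traits(b)
  r2 <- simulate_traits(b)
  expect_identical(r1, r2)
  expect_setequal(unique(r1$environment),
                  unique(paste(r1$location, r1$year, sep = "_")))
  expect_equal(nrow(r1), 40 * 2 * 3)

  # noise-free limit: record = env effect + genetic value
  cfg0 <- sim_config(n_founders = 20, n_families = 0, n_chromosomes = 1,
                     snps_per_chromosome = 20, n_traits = 1,
                     var_ge = 0, var_e = 0, n_environments = 1,
                     replicates_per_genotype = 2, seed = 32)
  b0 <- simulate_population(cfg0)
  r0 <- simulate_traits(b0)
  g <- b0$true_genetic_values[r0$genotype_id, 1]
  env_eff <- r0$value - g
  expect_lt(diff(range(env_eff)), 1e-10) # single shared env effect
})

test_that("unreplicated subpopulations get one tree and two years only", {
  cfg <- sim_config(n_founders = 12, n_families = 1, progeny_per_family = 6,
                    n_chromosomes = 1, snps_per_chromosome = 10,
                    n_traits = 1, n_environments = 4,
                    replicates_per_genotype = 3, seed = 33)
  b <- simulate_population(cfg)
  unrep <- names(b$family_map)[b$family_map == "F01"]
  r <- simulate_traits(b, unreplicated = unrep)
  sub <- r[r$genotype_id %in% unrep, ]
  expect_true(all(table(sub$genotype_id, sub$environment) == 1))
  expect_equal(length(unique(sub$environment)), 2)
  full <- r[!(r$genotype_id %in% unrep), ]
  expect_true(all(table(full$genotype_id, full$environment) == 3))
})

test_that("simulated variance components are recovered by REML downstream", {
  cfg <- sim_config(n_founders = 400, n_families = 0, n_chromosomes = 2,
                    snps_per_chromosome = 40, n_traits = 1,
                    var_g = 2, var_ge = 1, var_e = 1,
                    n_environments = 4, replicates_per_genotype = 2,
                    seed = 34)
  b <- simulate_population(cfg)
  r <- simulate_traits(b)
  fit <- fit_mixed_model(r, "trait1")
  expect_lt(abs(fit$varcomp[["g"]] - 2) / 2, 0.2)
  expect_lt(abs(fit$varcomp[["ge"]] - 1) / 1, 0.2)
  expect_lt(abs(fit$varcomp[["e"]] - 1) / 1, 0.2)
})

test_that("spectra carry the configured dimensions and signal behaviour", {
  cfg <- sim_config(n_founders = 50, n_families = 0, n_chromosomes = 2,
                    snps_per_chromosome = 30, n_traits = 1, seed = 41)
  b <- simulate_population(cfg)
  sp <- simulate_spectra(b)
  expect_equal(ncol(sp$values), 1380)
  expect_equal(range(sp$wavelengths), c(1050, 2500))

  # deterministic signal: identical genotypes give identical spectra
  cfg1 <- sim_config(n_founders = 10, n_families = 0, n_chromosomes = 1,
                     snps_per_chromosome = 5, n_traits = 1,
                     n_wavelengths = 100, genetic_signal_fraction = 1,
                     spectra_noise_sd = 0, maf_range = c(0.5, 0.5),
                     seed = 42)
  b1 <- simulate_population(cfg1)
  dup <- which(duplicated(b1$genotypes$dosages) |
                 duplicated(b1$genotypes$dosages, fromLast = TRUE))
  sp1 <- simulate_spectra(b1)
  key <- apply(b1$genotypes$dosages, 1, paste, collapse = "")
  for (k in unique(key[dup])) {
    rows <- which(key == k)
    expect_equal(sp1$values[rows[1], ], sp1$values[rows[2], ])
  }
})

test_that("zero genetic signal yields spectra kernels uncorrelated with G", {
  cfg <- sim_config(n_founders = 300, n_families = 0, n_chromosomes = 2,
                    snps_per_chromosome = 50, n_traits = 1,
                    n_wavelengths = 300, genetic_signal_fraction = 0,
                    spectra_noise_sd = 0.1, seed = 43)
  b <- simulate_population(cfg)
  sp <- simulate_spectra(b)
  G <- compute_grm(b$genotypes)
  H <- compute_phenomic_kernel(sp)
  off <- upper.tri(unclass(G))
  expect_lt(abs(cor(unclass(G)[off], unclass(H)[off])), 0.1)
})

test_that("sparse-set degradation calibrates overlap, missingness and discordance", {
  g <- toy_genotypes(n = 50, m = 200, seed = 51)
  # no corruption -> zero discordance
  s0 <- degrade_to_sparse_set(g, 1, 0, 0, seed = 1)
  expect_equal(non_reference_discordance(g$dosages, s0$dosages)$mean, 0)

  # calibrated discordance on 10,000 entries
  s1 <- degrade_to_sparse_set(g, 1, 0, 0.25, seed = 2)
  nrd <- non_reference_discordance(
    matrix(g$dosages, nrow = 1), matrix(s1$dosages, nrow = 1))$mean
  expect_lt(abs(nrd - 0.25), 0.03)

  # binomial retention count within 3 SD
  g2 <- toy_genotypes(n = 2, m = 5000, seed = 52)
  s2 <- degrade_to_sparse_set(g2, 0.024, 0, 0, seed = 3)
  expected <- 5000 * 0.024
  sd3 <- 3 * sqrt(5000 * 0.024 * 0.976)
  expect_lt(abs(ncol(s2$dosages) - expected), sd3)
  expect_error(degrade_to_sparse_set(g, 1.2, 0, 0), "rates")
})
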