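# shared fixture builders; everything is generated in code

# balanced one-way toy: 3 genotypes x 2 clonal replicates, one environment
balanced_toy <- function() {
  data.frame(genotype_id = rep(c("g1", "g2", "g3"), each = 2),
             environment = "L1_2020", trait = "t",
             tree_id = paste0("tree", 1:6),
             value = c(4, 6, 8, 10, 6, 8))
}

toy_genotypes <- function(n = 6, m = 20, seed = 1, maf = 0.3) {
  set.seed(seed)
  D <- matrix(rbinom(n * m, 2, maf), n, m,
              dimnames = list(sprintf("i%02d", 1:n), sprintf("s%03d", 1:m)))
  genotype_matrix(D, data.frame(snp = colnames(D), chrom = "1",
                                pos_bp = seq_len(m) * 100,
                                pos_cM = seq_len(m)))
}

toy_spectra <- function(n = 4, n_wl = 120, seed = 1) {
  set.seed(seed)
  wl <- seq(1050, 2500, length.out = n_wl)
  vals <- matrix(rnorm(n * n_wl), n, n_wl,
                 dimnames = list(sprintf("i%02d", 1:n), NULL))
  spectra_matrix(vals, wl)
}

# small family-structured population for prediction tests
small_population <- function(seed = 11, n_founders = 40, n_families = 5,
                             progeny = 8, snps = 40) {
  simulate_population(sim_config(
    n_founders = n_founders, n_families = n_families,
    progeny_per_family = progeny, snps_per_chromosome = snps,
    n_chromosomes = 3, n_traits = 1, seed = seed))
}

# multi-environment records whose genotype x environment cell means are
# exactly additive (interaction-free by construction): the REML estimate of
# the interaction variance is exactly zero, which exercises the
# singular-fit fallback deterministically
additive_records <- function(n_geno = 200, n_env = 3, reps = 2,
                             var_g = 2, var_e = 1, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_geno, 0, sqrt(var_g))
  env <- rnorm(n_env, 0, 1)
  rows <- expand.grid(gi = seq_len(n_geno), ei = seq_len(n_env))
  recs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    eps <- rnorm(reps, 0, sqrt(var_e))
    eps <- eps - mean(eps) # cell mean exactly g + env
    data.frame(genotype_id = sprintf("g%03d", rows$gi[i]),
               environment = sprintf("E%d", rows$ei[i]), trait = "t",
               tree_id = sprintf("t%d_%d_%d", rows$gi[i], rows$ei[i],
                                 seq_len(reps)),
               value = g[rows$gi[i]] + env[rows$ei[i]] + eps)
  }))
  rownames(recs) <- NULL
  recs
}

make_filter_toy <- function() {
  # 100 samples x 5 variants; only v1 survives every rule
  n <- 100
  dos <- matrix(0, n, 5, dimnames = list(sprintf("s%03d", 1:n),
                                         paste0("v", 1:5)))
  dos[1:10, 1] <- 1          # v1: maf 10/180 = 0.056 after 10 missing
  dos[91:100, 1] <- NA       # v1 missingness 0.1
  dos[1:30, 2] <- 1          # v2: healthy but an indel
  dos[1, 3] <- 1             # v3: maf 1/200 = 0.005 < 0.01
  dos[1:10, 4] <- 2
  dos[21:100, 4] <- NA       # v4: missingness 0.8 > 0.7
  dos[1:40, 5] <- 1          # v5: fine but unplaced chromosome "0"
  info <- data.frame(snp = paste0("v", 1:5),
                     chrom = c("1", "2", "3", "4", "0"),
                     pos = c(100, 200, 300, 400, 500),
                     type = c("SNP", "indel", "SNP", "SNP", "SNP"))
  variant_table(info, dos)
}

# genetic values consistent with a kernel: u ~ N(0, K * s2)
draw_from_kernel <- function(K, s2 = 1, jitter = 1e-6) {
  W <- unclass(K)
  drop(t(chol(W + diag(jitter, nrow(W)))) %*% rnorm(nrow(W))) * sqrt(s2)
}
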