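#' Simulation configuration for the synthetic orchard
#'
#' Collects every parameter of the synthetic population, trial and spectra
#' generators and validates it once. Defaults emulate the structure of a
#' perennial refererence population: a diverse accession panel plus ~10-20
#' progeny biparental families, linked biallelic SNPs on 17 chromosomes,
#' multi-environment clonal phenotypes and leaf NIR spectra on a
#' 1050-2500 nm grid (1,380 variables).
#'
#' @param n_founders number of unrelated panel accessions.
#' @param n_families number of biparental families.
#' @param progeny_per_family progeny per family (scalar or vector).
#' @param n_chromosomes number of chromosomes (default 17).
#' @param snps_per_chromosome SNPs simulated per chromosome.
#' @param chromosome_length_cM genetic length of each chromosome.
#' @param maf_range range of minor-allele frequencies, subset of (0, 0.5].
#' @param n_traits number of traits.
#' @param var_g,var_ge,var_e genotype, genotype-by-environment and residual
#'   variance components of the trait model (trait units squared).
#' @param n_environments number of location-by-year environments.
#' @param replicates_per_genotype clonal replicates (trees) per genotype and
#'   environment.
#' @param env_effect_sd standard deviation of the fixed environment effects.
#' @param tree_age_effect_per_year linear fixed effect of tree age.
#' @param n_qtl_per_trait QTL underlying each trait.
#' @param n_wavelengths spectral variables (default 1380 on 1050-2500 nm).
#' @param genetic_signal_fraction fraction of spectral basis-coefficient
#'   variance attributable to QTL dosages, in \[0, 1\].
#' @param spectra_noise_sd standard deviation of smooth spectral noise.
#' @param spectra_n_basis number of Gaussian basis functions.
#' @param seed integer seed fixing all randomness downstream.
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_founders = 270, n_families = 27,
                       progeny_per_family = 10, n_chromosomes = 17,
                       snps_per_chromosome = 100, chromosome_length_cM = 100,
                       maf_range = c(0.05, 0.5), n_traits = 3,
                       var_g = 1, var_ge = 0.25, var_e = 0.5,
                       n_environments = 4, replicates_per_genotype = 2,
                       env_effect_sd = 1, tree_age_effect_per_year = 0,
                       n_qtl_per_trait = 100, n_wavelengths = 1380,
                       genetic_signal_fraction = 0.5, spectra_noise_sd = 0.2,
                       spectra_n_basis = 30, seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    if (n_founders < 2 || n_chromosomes < 1 || snps_per_chromosome < 1)
      stop("population dimensions must be positive (>= 2 founders)")
    if (any(progeny_per_family < 1) || n_families < 0)
      stop("family sizes must be positive")
    if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
        maf_range[1] <= 0 || maf_range[2] > 0.5)
      stop("maf_range must be a subset of (0, 0.5]; monomorphic SNPs are disallowed")
    if (any(c(var_g, var_ge, var_e) < 0)) stop("variances must be >= 0")
    if (genetic_signal_fraction < 0 || genetic_signal_fraction > 1)
      stop("genetic_signal_fraction must lie in [0, 1]")
    if (n_environments < 1 || replicates_per_genotype < 1)
      stop("trial dimensions must be positive")
  })
  if (length(cfg$progeny_per_family) == 1L)
    cfg$progeny_per_family <- rep(cfg$progeny_per_family, cfg$n_families)
  if (length(cfg$progeny_per_family) != cfg$n_families)
    stop("progeny_per_family must have length 1 or n_families")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# uniform wavelength grid used for all spectra, 1050-2500 nm inclusive
wavelength_grid <- function(n) seq(1050, 2500, length.out = n)

#' Simulate phased founder genotypes
#'
#' Draws independent founder haplotypes per SNP with allele frequencies from
#' `maf_range`, places SNPs on `n_chromosomes` chromosomes with genetic (cM)
#' and physical (bp) positions, and retains phase for gamete formation.
#'
#' @param config a [sim_config()].
#' @param ids optional founder IDs (default `ACC0001`, ...).
#' @return a phased [genotype_matrix()].
#' @export
simulate_founders <- function(config, ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_founders
  m_chr <- config$snps_per_chromosome
  n_chr <- config$n_chromosomes
  L <- config$chromosome_length_cM
  map <- do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    cm <- sort(stats::runif(m_chr, 0, L))
    bp <- sort(sample.int(3e7, m_chr))
    data.frame(snp = sprintf("c%02d_p%08d", ch, bp), chrom = as.character(ch),
               pos_bp = bp, pos_cM = cm)
  }))
  m <- nrow(map)
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  if (is.null(ids)) ids <- sprintf("ACC%04d", seq_len(n))
  h1 <- matrix(stats::rbinom(n * m, 1, rep(p, each = n)), n, m,
               dimnames = list(ids, map$snp))
  h2 <- matrix(stats::rbinom(n * m, 1, rep(p, each = n)), n, m,
               dimnames = list(ids, map$snp))
  genotype_matrix(h1 + h2, map, haplotypes = list(h1 = h1, h2 = h2))
}

# One gamete per row: haplotype mosaic along each chromosome under the
# Haldane model (no interference). Crossover counts are Poisson in map
# length, which for SNP-to-SNP transmission is equivalent to independent
# switches with probability r = (1 - exp(-2d/100))/2 between adjacent SNPs.
make_gametes <- function(h1, h2, map, n_gametes) {
  m <- length(h1)
  gam <- matrix(0L, n_gametes, m)
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    d <- diff(map$pos_cM[j])
    r <- (1 - exp(-2 * d / 100)) / 2
    start <- stats::rbinom(n_gametes, 1, 0.5)
    if (length(j) > 1) {
      sw <- matrix(stats::rbinom(n_gametes * length(r), 1, rep(r, each = n_gametes)),
                   n_gametes, length(r))
      state <- (start + t(apply(cbind(0L, sw), 1, cumsum))) %% 2L
    } else {
      state <- matrix(start, n_gametes, 1)
    }
    pick1 <- state == 0L
    block <- matrix(rep(h1[j], each = n_gametes), n_gametes, length(j))
    block2 <- matrix(rep(h2[j], each = n_gametes), n_gametes, length(j))
    gam[, j] <- ifelse(pick1, block, block2)
  }
  gam
}

#' Simulate a biparental family by Mendelian gamete formation
#'
#' Each progeny receives one recombinant gamete from each phased parent;
#' crossovers follow the Haldane map function (Poisson, no interference).
#'
#' @param parents a phased [genotype_matrix()] containing both parents.
#' @param parent1,parent2 row IDs of the two parents in `parents`.
#' @param n_progeny family size.
#' @param seed integer seed.
#' @param ids optional progeny IDs.
#' @return a phased [genotype_matrix()] of the progeny.
#' @export
simulate_family <- function(parents, parent1, parent2, n_progeny, seed = NULL,
                            ids = NULL) {
  stopifnot(inherits(parents, "genotype_matrix"))
  if (!is_phased(parents))
    stop("parents must be phased (haplotypes required for gamete formation)")
  if (!all(c(parent1, parent2) %in% rownames(parents$dosages)))
    stop("parent IDs not found")
  if (!is.null(seed)) set.seed(seed)
  map <- parents$map
  g1 <- make_gametes(parents$haplotypes$h1[parent1, ],
                     parents$haplotypes$h2[parent1, ], map, n_progeny)
  g2 <- make_gametes(parents$haplotypes$h1[parent2, ],
                     parents$haplotypes$h2[parent2, ], map, n_progeny)
  if (is.null(ids)) ids <- sprintf("%s_x_%s_%03d", parent1, parent2,
                                   seq_len(n_progeny))
  dimnames(g1) <- dimnames(g2) <- list(ids, map$snp)
  genotype_matrix(g1 + g2, map, haplotypes = list(h1 = g1, h2 = g2))
}

#' Simulate a full population: accession panel plus biparental families
#'
#' Builds the founder panel, mates randomly chosen panel accessions to
#' produce the requested biparental families, assigns per-trait QTL effects
#' and scales true genetic values so the population genetic variance equals
#' `var_g` for every trait.
#'
#' @param config a [sim_config()].
#' @return an object of class `population_bundle` with elements `genotypes`
#'   (all individuals), `family_map` (ID to family label, `"ACCESSION"` for
#'   panel members), `pedigree`, `true_genetic_values` (individuals x traits)
#'   and `qtl_effects`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  founders <- simulate_founders(config)
  acc_ids <- rownames(founders$dosages)
  fam_ids <- character(0)
  pedigree <- list()
  hap1 <- founders$haplotypes$h1
  hap2 <- founders$haplotypes$h2
  dos <- founders$dosages
  family_map <- stats::setNames(rep("ACCESSION", length(acc_ids)), acc_ids)
  if (config$n_families > 0) {
    n_par <- 2 * config$n_families
    if (n_par > length(acc_ids))
      stop("not enough founders to draw distinct family parents")
    pars <- matrix(sample(acc_ids, n_par), ncol = 2)
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("F%02d", f)
      np <- config$progeny_per_family[f]
      kids <- simulate_family(founders, pars[f, 1], pars[f, 2], np,
                              ids = sprintf("%s_%03d", fam, seq_len(np)))
      dos <- rbind(dos, kids$dosages)
      hap1 <- rbind(hap1, kids$haplotypes$h1)
      hap2 <- rbind(hap2, kids$haplotypes$h2)
      family_map <- c(family_map,
                      stats::setNames(rep(fam, np), rownames(kids$dosages)))
      for (id in rownames(kids$dosages))
        pedigree[[id]] <- c(pars[f, 1], pars[f, 2])
    }
  }
  genotypes <- genotype_matrix(dos, founders$map,
                               haplotypes = list(h1 = hap1, h2 = hap2))
  m <- ncol(dos)
  traits <- sprintf("trait%d", seq_len(config$n_traits))
  tgv <- matrix(0, nrow(dos), length(traits),
                dimnames = list(rownames(dos), traits))
  qtl_effects <- vector("list", length(traits))
  names(qtl_effects) <- traits
  for (tr in traits) {
    idx <- sort(sample.int(m, min(config$n_qtl_per_trait, m)))
    eff <- stats::rnorm(length(idx))
    g <- drop(dos[, idx, drop = FALSE] %*% eff)
    s <- stats::sd(g)
    if (s > 0 && config$var_g > 0) {
      scl <- sqrt(config$var_g) / s
    } else scl <- 0
    eff <- eff * scl
    g <- (g - mean(g)) * scl
    tgv[, tr] <- g
    qtl_effects[[tr]] <- data.frame(snp_index = idx, effect = eff)
  }
  structure(list(genotypes = genotypes, family_map = family_map,
                 pedigree = pedigree, true_genetic_values = tgv,
                 qtl_effects = qtl_effects, config = config),
            class = "population_bundle")
}

#' @export
print.population_bundle <- function(x, ...) {
  nf <- length(setdiff(unique(x$family_map), "ACCESSION"))
  cat(sprintf("<population_bundle> %d individuals (%d accessions, %d families), %d SNPs, %d trait(s)\n",
              nrow(x$genotypes$dosages), sum(x$family_map == "ACCESSION"), nf,
              ncol(x$genotypes$dosages), ncol(x$true_genetic_values)))
  invisible(x)
}

#' Extend a population with sibling progeny (breeding-material emulation)
#'
#' Adds `n_extra` full-sib progeny to each requested family, drawn from the
#' same parents under the same genetic map, and extends the family map,
#' pedigree and true genetic values consistently. The new individuals are
#' labelled with `prefix` + family name, emulating related breeding-program
#' material that can be added to training sets.
#'
#' @param bundle a [simulate_population()] result.
#' @param families family labels to extend.
#' @param n_extra new progeny per family.
#' @param prefix family-label prefix for the new material (default "B").
#' @param seed integer seed.
#' @return an extended `population_bundle`.
#' @export
add_sibling_progeny <- function(bundle, families, n_extra, prefix = "B",
                                seed = NULL) {
  stopifnot(inherits(bundle, "population_bundle"))
  if (!is.null(seed)) set.seed(seed)
  geno <- bundle$genotypes
  dos <- geno$dosages
  hap1 <- geno$haplotypes$h1
  hap2 <- geno$haplotypes$h2
  family_map <- bundle$family_map
  pedigree <- bundle$pedigree
  for (fam in families) {
    members <- names(family_map)[family_map == fam]
    if (!length(members)) stop("unknown family: ", fam)
    pars <- pedigree[[members[1]]]
    if (is.null(pars)) stop("family ", fam, " has no recorded parents")
    newfam <- paste0(prefix, fam)
    kids <- simulate_family(geno, pars[1], pars[2], n_extra,
                            ids = sprintf("%s_%03d", newfam,
                                          seq_len(n_extra)))
    dos <- rbind(dos, kids$dosages)
    hap1 <- rbind(hap1, kids$haplotypes$h1)
    hap2 <- rbind(hap2, kids$haplotypes$h2)
    family_map <- c(family_map,
                    stats::setNames(rep(newfam, n_extra),
                                    rownames(kids$dosages)))
    for (id in rownames(kids$dosages)) pedigree[[id]] <- pars
  }
  genotypes <- genotype_matrix(dos, geno$map,
                               haplotypes = list(h1 = hap1, h2 = hap2))
  # genetic values for the new individuals on the same centred scale:
  # recover the centring constant from any existing individual
  traits <- colnames(bundle$true_genetic_values)
  tgv <- matrix(0, nrow(dos), length(traits),
                dimnames = list(rownames(dos), traits))
  ref_id <- rownames(bundle$true_genetic_values)[1]
  for (tr in traits) {
    q <- bundle$qtl_effects[[tr]]
    raw <- drop(dos[, q$snp_index, drop = FALSE] %*% q$effect)
    offset <- raw[ref_id] - bundle$true_genetic_values[ref_id, tr]
    tgv[, tr] <- raw - offset
  }
  structure(list(genotypes = genotypes, family_map = family_map,
                 pedigree = pedigree, true_genetic_values = tgv,
                 qtl_effects = bundle$qtl_effects, config = bundle$config),
            class = "population_bundle")
}

#' Simulate multi-environment clonal trial records
#'
#' Generates long-format tree-level records
#' `value = env effect + age * slope + g + ge + e` at the configured
#' variance components. Clonal replicates within an environment share the
#' genotype and interaction effects and draw independent residuals.
#' Genotypes listed in `unreplicated` emulate early-stage breeding material:
#' a single tree, observed only in the last two environments.
#'
#' @param bundle a [simulate_population()] result.
#' @param config a [sim_config()] (defaults to the bundle's own).
#' @param unreplicated optional character vector of genotype IDs grown
#'   without clonal replication and for two years only.
#' @param seed integer seed (defaults to `config$seed + 1`).
#' @return a `data.frame` of phenotype records with columns `genotype_id`,
#'   `family`, `location`, `year`, `environment`, `tree_id`, `tree_age`,
#'   `trait`, `value`.
#' @export
simulate_traits <- function(bundle, config = bundle$config,
                            unreplicated = NULL, seed = NULL) {
  stopifnot(inherits(bundle, "population_bundle"))
  ids <- rownames(bundle$genotypes$dosages)
  if (length(ids) == 0) stop("bundle contains no genotypes")
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  ne <- config$n_environments
  nr <- config$replicates_per_genotype
  locs <- paste0("L", rep(seq_len(ceiling(ne / 5)), each = 5))[seq_len(ne)]
  years <- rep(2018:2022, length.out = ne)
  envs <- paste(locs, years, sep = "_")
  env_eff <- stats::rnorm(ne, 0, config$env_effect_sd)
  traits <- colnames(bundle$true_genetic_values)
  planted <- stats::setNames(sample(2014:2016, length(ids), replace = TRUE), ids)
  out <- vector("list", length(traits))
  unrep <- ids %in% unreplicated
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    g <- bundle$true_genetic_values[, tr]
    ge <- matrix(stats::rnorm(length(ids) * ne, 0, sqrt(config$var_ge)),
                 length(ids), ne, dimnames = list(ids, envs))
    recs <- vector("list", ne)
    for (e in seq_len(ne)) {
      use <- if (any(unrep)) (!unrep) | (e > ne - 2) else rep(TRUE, length(ids))
      reps_per <- ifelse(unrep[use], 1L, nr)
      gid <- rep(ids[use], times = reps_per)
      repno <- sequence(reps_per)
      age <- years[e] - planted[gid]
      eps <- stats::rnorm(length(gid), 0, sqrt(config$var_e))
      recs[[e]] <- data.frame(
        genotype_id = gid,
        family = unname(bundle$family_map[gid]),
        location = locs[e], year = years[e], environment = envs[e],
        tree_id = paste(gid, envs[e], repno, sep = "."),
        tree_age = age, trait = tr,
        value = env_eff[e] + age * config$tree_age_effect_per_year +
          g[gid] + ge[gid, e] + eps,
        row.names = NULL)
    }
    out[[ti]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate leaf NIR spectra with a controllable genetic signal
#'
#' Each spectrum is a smooth baseline plus a sum of Gaussian basis functions
#' whose coefficients mix a standardized genetic score (a linear combination
#' of QTL dosages, weight `genetic_signal_fraction`) with independent
#' individual noise, plus smooth high-frequency noise. At
#' `genetic_signal_fraction = 1` and zero noise the spectrum is a
#' deterministic function of the genotype.
#'
#' @param bundle a [simulate_population()] result.
#' @param trait trait whose QTL drive the signal (default first trait).
#' @param config a [sim_config()] (defaults to the bundle's own).
#' @param seed integer seed (defaults to `config$seed + 2`).
#' @return a raw [spectra_matrix()] on the 1050-2500 nm grid.
#' @export
simulate_spectra <- function(bundle, trait = NULL, config = bundle$config,
                             seed = NULL) {
  stopifnot(inherits(bundle, "population_bundle"))
  gsf <- config$genetic_signal_fraction
  if (gsf < 0 || gsf > 1) stop("genetic_signal_fraction must lie in [0, 1]")
  if (is.null(trait)) trait <- names(bundle$qtl_effects)[1]
  if (is.null(seed)) seed <- config$seed + 2L
  set.seed(seed)
  ids <- rownames(bundle$genotypes$dosages)
  n <- length(ids)
  wl <- wavelength_grid(config$n_wavelengths)
  nb <- config$spectra_n_basis
  centers <- seq(min(wl), max(wl), length.out = nb)
  width <- diff(range(wl)) / nb
  basis <- outer(wl, centers, function(w, c0) exp(-0.5 * ((w - c0) / width)^2))
  qtl <- bundle$qtl_effects[[trait]]
  if (is.null(qtl)) stop("unknown trait: ", trait)
  D <- bundle$genotypes$dosages[, qtl$snp_index, drop = FALSE]
  # per-basis genetic scores: random QTL loadings, standardized across the
  # population so the signal fraction is exact in expectation
  Wq <- matrix(stats::rnorm(ncol(D) * nb), ncol(D), nb)
  S <- D %*% Wq
  S <- scale(S)
  S[, attr(S, "scaled:scale") == 0] <- 0
  Z <- matrix(stats::rnorm(n * nb), n, nb)
  coef <- sqrt(gsf) * S + sqrt(1 - gsf) * Z
  baseline <- 0.5 + 0.3 * sin(2 * pi * (wl - min(wl)) / diff(range(wl)))
  vals <- matrix(rep(baseline, each = n), n, length(wl)) +
    0.05 * coef %*% t(basis)
  if (config$spectra_noise_sd > 0) {
    noise <- matrix(stats::rnorm(n * length(wl)), n, length(wl))
    ker <- stats::dnorm(seq(-3, 3, length.out = 31))
    ker <- ker / sum(ker)
    noise <- t(apply(noise, 1, function(r)
      stats::filter(r, ker, sides = 2, circular = TRUE)))
    vals <- vals + config$spectra_noise_sd * noise
  }
  rownames(vals) <- ids
  spectra_matrix(vals, wl, provenance = "raw")
}

#' Degrade an array-resolution genotype set to a sparse RADseq-like set
#'
#' Retains a random fraction of SNP positions, masks a fraction of entries
#' as missing, and perturbs dosages so that the downstream non-reference
#' discordance against the source approximates `discordance_rate`. Masked
#' entries are filled with the per-SNP mean dosage (a naive stand-in for a
#' full imputation step; the masking pattern is returned so callers can plug
#' in their own imputation).
#'
#' @param genotypes a [genotype_matrix()].
#' @param overlap_fraction probability that a SNP position is retained.
#' @param missing_rate probability that a retained entry is masked.
#' @param discordance_rate target mean non-reference discordance.
#' @param seed integer seed.
#' @return a `genotype_matrix` over the retained SNPs (numeric dosages after
#'   mean fill), with attributes `masked` (logical matrix) and `perturbed`.
#' @export
degrade_to_sparse_set <- function(genotypes, overlap_fraction = 1,
                                  missing_rate = 0, discordance_rate = 0,
                                  seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  for (v in c(overlap_fraction, missing_rate, discordance_rate))
    if (v < 0 || v > 1) stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(genotypes$dosages)
  keep <- which(stats::runif(m) < overlap_fraction)
  if (length(keep) == 0) stop("no SNP positions retained; raise overlap_fraction")
  dos <- genotypes$dosages[, keep, drop = FALSE]
  map <- genotypes$map[keep, , drop = FALSE]
  perturbed <- matrix(FALSE, nrow(dos), ncol(dos))
  if (discordance_rate > 0) {
    t <- discordance_rate
    pi_nonref <- mean(dos %in% c(1, 2))
    q <- t * pi_nonref / ((1 - t) + t * pi_nonref)
    perturbed <- matrix(stats::runif(length(dos)) < q, nrow(dos), ncol(dos))
    idx <- which(perturbed)
    if (length(idx)) {
      old <- dos[idx]
      shift <- sample(1:2, length(idx), replace = TRUE)
      dos[idx] <- (old + shift) %% 3
    }
  }
  masked <- matrix(stats::runif(length(dos)) < missing_rate,
                   nrow(dos), ncol(dos))
  dos[masked] <- NA
  fill <- colMeans(dos, na.rm = TRUE)
  fill[is.nan(fill)] <- 1
  na_idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(na_idx)) dos[na_idx] <- fill[na_idx[, 2]]
  out <- genotype_matrix(dos, map)
  attr(out, "masked") <- masked
  attr(out, "perturbed") <- perturbed
  out
}
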