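---
title: "Genomic and phenomic prediction for clonal breeding material: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and phenomic prediction for clonal breeding material: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpred)
```

`clonalpred` evaluates genomic and phenomic prediction for clonally
propagated perennial breeding material: apple-like populations in which a
diverse accession panel coexists with biparental families, genotypes are
replicated as grafted trees across multi-environment trials, and candidate
predictors include SNP arrays, sparse RADseq-derived genotypes and leaf
near-infrared (NIR) spectra. Everything runs end-to-end on a synthetic
orchard generator, so every stage is testable without any external data.

## The phenotypic model and clonal values

Tree-level records are modelled per trait with the linear mixed model

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}\mathbf{b} + \boldsymbol\varepsilon,$$

with a fixed effect of environment (a location-by-year combination),
optionally a linear fixed effect of tree age, and random effects of
genotype and genotype-by-environment interaction,
$b_g \sim N(0, \sigma^2_g)$, $b_{ge} \sim N(0, \sigma^2_{ge})$,
$\varepsilon \sim N(0, \sigma^2_\varepsilon)$. Fitting is by REML through
`lme4`, with optimizer tolerances tightened (`xtol_abs = 1e-12`,
`ftol_abs = 1e-14`) so that on balanced designs the estimates agree with
the ANOVA closed form to well below `1e-6`. The conditional means (BLUPs)
of the genotype effect are the *clonal values* used as responses by all
prediction models; they are centered by construction.

Clonal mean heritability is
$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/n_e +
\sigma^2_\varepsilon/(n_e\,\bar n_r)},$$
where $n_e$ is the number of environments and $\bar n_r$ the mean number
of clonal replicates. `clonal_mean_h2()` evaluates this directly;
`variance_decomposition()` derives it from a fitted model. $\bar n_r$ is
computed as the mean replicate count per genotype per environment (the
mean over non-empty genotype-by-environment cells); counting overall
replicates instead would conflate environments with replication.

Quality control mirrors common practice for multi-environment clonal
trials:

* trait-environment combinations with environment-specific clonal mean
  heritability below 0.1 (strictly) are dropped before modelling
  (`filter_trait_environments()`);
* outliers are flagged on conditional residuals standardized by
  $1.4826 \times$ MAD with Bonferroni-Holm-adjusted two-sided normal tests
  (`detect_outliers()`, default $\alpha = 0.05$). Several variants of this
  residual-based scheme circulate; the MAD-standardized Bonferroni-Holm
  variant was adopted because it is robust to the very outliers it hunts
  and needs no refitting per candidate. When the MAD is zero (all
  residuals identical) nothing is flagged. The caller refits after removal
  (`fit_cleaned_model()` wraps fit-flag-refit).

**Singular interaction fits.** When the interaction variance collapses the
term is dropped and the model refit. Singularity is declared when
`lme4::isSingular()` reports a boundary fit *or* when
$\hat\sigma^2_{ge}$ falls below $10^{-6}$ of the total variance — the
boundary can be approached to within numerical noise without being hit
exactly. A caveat for testing this mechanism: when the true
$\sigma^2_{ge}$ is zero, the REML estimator is the positive part of an
asymptotically symmetric estimator and lands on the boundary only about
half the time. The test suite therefore exercises the fallback on records
whose genotype-by-environment cell means are exactly additive (the
interaction sum of squares is identically zero), which triggers a boundary
fit on every seed; ordinary simulations at $\sigma^2_{ge} = 0$ would test
the estimator's sampling distribution, not the fallback.

## Kernels

The genomic relationship matrix follows VanRaden: dosage columns centered
by $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$, cross-product
divided by the number of retained SNPs. Monomorphic SNPs are dropped and
missing dosages mean-filled per SNP (the standard VanRaden treatment;
for sparse genotype sets this mean fill also stands in for a full
imputation step, with the masking pattern exposed so a real imputer can be
plugged in).

Phenomic kernels are built identically from spectra columns. Seven spectra
matrices feed them (`preprocess_suite()`): raw; column-autoscaled
("normalized"); detrended (per-spectrum standard normal variate followed by
removal of the least-squares quadratic in wavelength); and first/second
Savitzky-Golay derivatives of the raw and normalized matrices (first
derivative: filter order 2, length 37; second: order 3, length 61, via the
`signal` package). Choices worth stating:

* "Normalized" is interpreted as *column-wise* autoscaling across
  individuals — deliberately distinct from the row-wise SNV inside
  detrending, since the two appear as different pre-processing products;
  `normalize_spectra(by = "row")` switches the convention.
* Sample (n−1) standard deviations are used throughout, matching common
  chemometrics implementations.
* Derivatives are per index step of the uniform wavelength grid, not per
  nm; this only rescales the kernel proportionally, which kernel
  standardization absorbs.
* Filter edges are handled by the polynomial fitted to the first/last full
  window, so every matrix keeps the full variable count (1,380 on the
  default 1050–2500 nm grid).
* The quadratic detrending basis is built on standardized wavelengths;
  raw nm values near $2.5 \times 10^3$ squared make the normal equations
  numerically singular.

## The kernel prediction model

Prediction uses the Bayesian kernel regression
$$\mathbf{y} = \mathbf{1}\mu + \mathbf{u} + \boldsymbol\varepsilon, \qquad
\mathbf{u} \sim N(\mathbf{0}, \mathbf{K}\sigma^2_u), \quad
\boldsymbol\varepsilon \sim N(\mathbf{0}, \mathbf{I}\sigma^2_\varepsilon),$$
the RKHS formulation of G-BLUP, with $\mathbf{K}$ a genomic ($\mathbf{G}$)
or phenomic ($\mathbf{H}$) kernel. The combined model adds two independent
kernel effects, $\mathbf{u} = \mathbf{u}_1 + \mathbf{u}_2$ with
$\mathbf{u}_1 \sim N(\mathbf{0}, \mathbf{G}\sigma^2_{u_1})$ and
$\mathbf{u}_2 \sim N(\mathbf{0}, \mathbf{H}\sigma^2_{u_2})$.

`fit_kernel_model()` samples this model by Gibbs. Implementation choices:

* Each kernel is eigendecomposed once, $\mathbf{K} = \mathbf{U}
  \mathbf{D}\mathbf{U}^\top$ (components below $10^{-8}$ of the leading
  eigenvalue dropped), and the effect is sampled in the eigenbasis
  $\mathbf{u} = \mathbf{B}\boldsymbol\delta$, $\mathbf{B} =
  \mathbf{U}\mathbf{D}^{1/2}$: because $\mathbf{B}^\top\mathbf{B} =
  \mathbf{D}$ is diagonal, the conditional posterior of
  $\boldsymbol\delta$ factorizes and each sweep costs two matrix-vector
  products per kernel.
* Variances carry scaled-inverse-$\chi^2$ priors with 5 degrees of freedom
  and scales set so the prior expected share of the response variance is
  0.5 for the kernel terms jointly (split equally among kernels) and 0.5
  for the residual — standard Bayesian-RKHS defaults.
* Validation individuals are carried with masked (NA) responses and imputed
  by data augmentation each iteration, so every individual in the kernel
  receives a posterior-mean prediction; this matches the usage pattern of
  the common RKHS software and gives the same answer as covariance
  projection in the closed-form limit.
* Default sampler settings are 12,000 iterations, burn-in 2,000, thinning
  5; one chain, with a crude effective-sample-size warning on the variance
  ratio (suppressible via `ess_warning = FALSE` for deliberately short
  chains). The seed is recorded in the fit.

Two independent cross-checks are kept as separate code paths:
`blup_oracle()` solves the mixed-model equations exactly for fixed
variances (also the definition of correctness for the sampler: posterior
means must track it when variances are well identified), and
`kernel_reml()` profiles the REML likelihood over the variance ratio(s) in
the rotated basis. `sampler_config(method = "blup")` routes a scenario
through REML + oracle instead of the sampler — deterministic and roughly
an order of magnitude faster, useful for large grids.

Predictive ability is the Pearson correlation between clonal values and
predictions in the validation set. Correlations are invariant to the
intercept, so whether $\mu + u$ or $u$ alone is correlated is immaterial.
If either vector is constant the correlation is undefined: the value is
returned as flagged `NA`, excluded from averages, and counted in the
diagnostics attached to result tables.

## Validation schemes

* **LOFO** (leave-one-family-out): one split per validation family;
  ability per family (LOFO1) or pooled across all validation families
  (LOFO2). LOFO1 reflects within-family ranking only; LOFO2 additionally
  credits between-family differences, so it is systematically the larger
  of the two under family structure.
* **single_block**: all designated validation families as one validation
  set (not a leave-one-family-out in a strict sense; both ability flavours
  are still computed).
* **CV**: repeated k-fold cross-validation, folds balanced to within one
  member, assignment RNG isolated from the sampler RNG. Ability is
  computed per repetition. `cv_target_families` restricts the genotypes on
  which ability is *assessed* (everyone is still predicted): this serves
  grid designs that validate on specific family sets, and it keeps
  scheme comparisons honest — CV pooled over synthetic founders with no
  relatives anywhere would confound the scheme contrast with a target-set
  difference, because fully unrelated simulated founders are harder to
  predict than real panel accessions, which are themselves mutually
  related.

Every split masks validation responses before fitting and a programmatic
leakage check asserts that no masked genotype contributes an unmasked
response to training. `run_scenario_grid()` resolves every scenario
(kernels, traits, families) before any model runs, then emits a tidy table
of abilities with per-scenario diagnostics; grids are declarative lists of
`scenario()` objects, so large designs are configuration, not code.

## Genotype QC and concordance

`filter_variants()` applies, in order: genotype-level depth masking
(calls under 4 reads set missing), variant mean-depth (≥ 4), removal of
indels and multiallelic variants, minor allele frequency (≥ 0.01),
assignment to chromosomes 1–17, variant missingness (≤ 0.7) and sample
missingness (≤ 0.7), reporting counts removed per rule. The relative order
of the MAF and missingness rules is fixed as listed; the narrative order
of the filters is otherwise preserved.

`overlap_by_position()` intersects datasets on (chromosome, position),
keeps matching ref/alt pairs, flips dosages ($2 - d$) for swapped pairs,
and drops strand-ambiguous (A/T, C/G) or inconsistent pairs rather than
guessing; duplicated positions within a dataset are dropped with a
warning.

Non-reference discordance is
$\mathrm{NRD} = m / (m + \mathrm{het~matches} + \mathrm{hom\text{-}alt~matches})$
with $m$ the count of discordant dosage pairs of any kind —
homozygous-reference matches are excluded from the denominator. Dosage
$r^2$ is the squared Pearson correlation per sample. Missing entries are
excluded pairwise in both metrics; samples with empty denominators are
flagged undefined and excluded from means.

## Population structure

PCA runs on column-centered dosages. IBS similarity per SNP is
$1 - |d_1 - d_2|/2$ (equivalent to allele sharing for biallelic loci),
averaged over SNPs; genetic distance is one minus IBS. The k-NN network
(default $k = 30$) links every genotype to its nearest neighbours, takes
the undirected union, and breaks distance ties by stable ID order, so node
degrees lie in $[1, 2k]$ and the graph is reproducible without a seed.

The number of significant components comes from a modified Horn parallel
analysis (Glorfeld variant): retain leading components whose observed
correlation-matrix eigenvalue exceeds the $(1-\alpha)$ quantile
($\alpha = 0.01$, 10,000 replicates by default; tests use 500) of
eigenvalues from independently column-permuted replicates — permutation
preserves marginal distributions while destroying correlation.

Genetic contribution scores are computed as
$gc_j = \sum_{i \le k} w_i\,|\mathrm{cor}(\mathbf{a}_j, \mathbf{v}_i)|$
with $\mathbf{a}_j$ the $j$-th row of the relationship matrix,
$\mathbf{v}_i$ its $i$-th eigenvector and $w_i = \lambda_i / \sum_{l\le k}
\lambda_l$. The eigenvalue weighting over the first $k$ components is a
reimplementation choice (the originating method is summarized rather than
printed in the sources this follows); it is isolated in one function for
easy substitution. Scores lie in $[0, 1]$. Near-constant eigenvectors
(e.g. the leading eigenvector of an equicorrelated matrix) make the
correlation undefined and contribute zero.

## The synthetic orchard generator

The generator emulates the statistical structure the analysis assumes:

* **Founders**: independent biallelic SNPs on 17 chromosomes (default 100
  per chromosome, 100 cM each), allele frequencies uniform on the
  configured MAF range (default 0.05–0.5; monomorphic SNPs are disallowed),
  phase retained.
* **Families**: gametes form by Poisson crossovers under the Haldane model
  (no interference), implemented as SNP-to-SNP switches with probability
  $r = (1 - e^{-2d/100})/2$ — mathematically identical to the Poisson
  process and closed-form testable. Progeny are Mendelian by construction.
  `add_sibling_progeny()` extends families with full sibs to emulate
  related breeding-program material.
* **Traits**: per-trait QTL (default 100) with standard-normal effects
  rescaled so the population genetic variance equals $\sigma^2_g$ exactly;
  within-family variance is left emergent from QTL segregation rather than
  set directly, since no external value exists for it. Records are
  env effect + age slope + $g$ + $ge$ + $\varepsilon$ at configured
  variances; clonal replicates share $g$ and $ge$ and draw independent
  residuals. Default variance ratios ($\sigma^2_g, \sigma^2_{ge},
  \sigma^2_\varepsilon$) = (1, 0.25, 0.5) put clonal mean heritability
  near 0.9 for a four-environment, two-replicate design — the upper-middle
  of the range observed for well-heritable fruit traits. An
  `unreplicated` flag restricts designated genotypes to one tree and the
  last two environments, emulating early-stage breeding material.
* **Spectra**: smooth baseline plus 30 Gaussian basis functions on a
  uniform 1050–2500 nm grid (default 1,380 variables); basis coefficients
  mix a standardized genetic score (linear in QTL dosages, weight
  `genetic_signal_fraction`) with independent noise, plus smoothed
  high-frequency noise. At fraction 1 and zero noise, spectra are a
  deterministic function of genotype; at fraction 0 the phenomic kernel is
  uncorrelated with $\mathbf{G}$.
* **Sparse sets**: `degrade_to_sparse_set()` retains a binomial fraction
  of positions, masks entries, and perturbs dosages at the rate
  $q = t\pi / ((1-t) + t\pi)$ ($\pi$ the non-reference fraction), which
  makes the downstream NRD converge to the target $t$.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: linkage disequilibrium among founders beyond
family structure (founder SNPs are drawn independently), selection and
assortative mating, genotyping error structure of real arrays, spatial
field trends (the framework accepts externally spatially-adjusted tree
values instead), dominance and epistasis, and real NIRS chemistry
(spectral signal is a generic linear-in-dosage construction). Qualitative
conclusions (scheme orderings, enrichment directions) transfer; absolute
ability levels do not.

## Problem sizes and numerical choices in the test suite

The acceptance-style checks run at desk scale, chosen to keep the full
suite within a few minutes while leaving the assertions well identified: a
study population of 100 accessions plus 20 families of 15 progeny (1,700
SNPs, three traits, four environments), sampler settings reduced to 700
iterations (burn-in 200, thinning 2) for scenario grids, full 12,000
iteration chains where sampler accuracy itself is under test, and 500
parallel-analysis replicates. Variance-component recovery uses 500
genotypes by four environments by two replicates. Heritability recovery is
asserted on the family-structured population: with an unstructured,
near-identity kernel the variance ratio is weakly identified at any
realistic sample size, and its estimation error would dominate the check.

Other numerical conventions: kernels are symmetrized and validated to
`1e-10`; eigen-components below `1e-8` of the leading eigenvalue are
treated as null space; the variance floor of the mixed models is lme4's;
correlation undefinedness is flagged rather than zero-filled; fold
assignment, gamete formation, trait noise and the sampler draw from
separate seeded streams so stages are independently reproducible.
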