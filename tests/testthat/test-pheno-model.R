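# ANOVA method-of-moments oracle for balanced one-way designs
anova_oneway <- function(values, genotypes) {
  r <- length(values) / length(unique(genotypes))
  means <- tapply(values, genotypes, mean)
  msb <- r * var(means)
  msw <- sum((values - means[as.character(genotypes)])^2) /
    (length(values) - length(means))
  c(g = max((msb - msw) / r, 0), e = msw)
}

test_that("REML on the balanced toy matches the ANOVA closed form", {
  toy <- balanced_toy()
  fit <- fit_mixed_model(toy, "t")
  oracle <- anova_oneway(toy$value, toy$genotype_id)
  expect_equal(fit$varcomp[["g"]], oracle[["g"]], tolerance = 1e-6)
  expect_equal(fit$varcomp[["e"]], oracle[["e"]], tolerance = 1e-6)
  cv <- clonal_values(fit)
  # shrinkage: var_g/(var_g + var_e/r) * (mean_i - grand mean)
  expect_equal(unname(cv[c("g1", "g2", "g3")]), c(-1.5, 1.5, 0),
               tolerance = 1e-6)
  expect_lt(abs(mean(cv)), 1e-8)
})

test_that("REML equals ANOVA estimators across random balanced one-way designs", {
  set.seed(77)
  for (i in 1:4) {
    ng <- sample(5:12, 1); r <- sample(2:4, 1)
    g <- rep(sprintf("g%02d", 1:ng), each = r)
    y <- rnorm(ng, 0, 2)[rep(1:ng, each = r)] + rnorm(ng * r)
    d <- data.frame(genotype_id = g, environment = "E1", trait = "t",
                    tree_id = seq_along(g), value = y)
    oracle <- anova_oneway(y, g)
    if (oracle[["g"]] <= 0) next # boundary case: skip interior comparison
    fit <- fit_mixed_model(d, "t")
    expect_equal(fit$varcomp[["g"]], oracle[["g"]], tolerance = 1e-6)
    expect_equal(fit$varcomp[["e"]], oracle[["e"]], tolerance = 1e-6)
  }
})

test_that("degenerate responses and confounded fixed effects are rejected", {
  toy <- balanced_toy()
  toy$value <- 5
  expect_error(fit_mixed_model(toy, "t"), "zero-variance")
  d <- balanced_toy()
  d$tree_age <- d$value * 0 + as.numeric(factor(d$environment)) # constant
  expect_error(fit_mixed_model(d, "t", include_age = TRUE), "confounded")
})

test_that("singular GxE fits fall back to the genotype-only model", {
  r <- additive_records(n_geno = 150, n_env = 3, reps = 2, seed = 88)
  fit <- fit_mixed_model(r, "t")
  expect_true(fit$singular_fit)
  expect_equal(fit$varcomp[["ge"]], 0)
  expect_lt(abs(fit$varcomp[["g"]] - 2) / 2, 0.3)
})

test_that("environment-specific heritability covers the closed form and limits", {
  toy <- balanced_toy()
  expect_equal(env_specific_heritability(toy, "t", "L1_2020"), 0.75,
               tolerance = 1e-6)
  noise_free <- toy
  noise_free$value <- rep(c(1, 5, 9), each = 2)
  expect_equal(env_specific_heritability(noise_free, "t", "L1_2020"), 1)
  flat <- toy
  flat$value <- 3
  expect_equal(env_specific_heritability(flat, "t", "L1_2020"), 0)
  single <- toy[toy$genotype_id == "g1", ]
  expect_error(env_specific_heritability(single, "t", "L1_2020"),
               ">= 2 genotypes")
})

test_that("trait-environment filtering drops only low-heritability combinations", {
  set.seed(5)
  good <- data.frame(genotype_id = rep(sprintf("g%d", 1:10), each = 2),
                     environment = "E1", trait = "t", tree_id = 1:20,
                     value = rep(rnorm(10, 0, 3), each = 2) + rnorm(20, 0, 0.5))
  bad <- good
  bad$environment <- "E2"
  bad$value <- rep(c(1, -1), 10) # genotype means all zero: heritability 0
  records <- rbind(good, bad)
  records$tree_id <- seq_len(nrow(records))
  out <- filter_trait_environments(records, threshold = 0.1)
  rep_tab <- attr(out, "report")
  expect_true(rep_tab$dropped[rep_tab$environment == "E2"])
  expect_false(rep_tab$dropped[rep_tab$environment == "E1"])
  expect_setequal(unique(out$environment), "E1")

  # boundary: exactly at threshold is retained (strict <)
  h1 <- rep_tab$h2[rep_tab$environment == "E1"]
  out2 <- filter_trait_environments(records, threshold = h1)
  expect_false(attr(out2, "report")$dropped[
    attr(out2, "report")$environment == "E1"])

  # all combinations clean -> identity
  out3 <- filter_trait_environments(good, threshold = 0.1)
  expect_equal(nrow(out3), nrow(good))
})

test_that("outlier detection flags gross outliers and respects degenerate cases", {
  set.seed(9)
  n <- 100
  d <- data.frame(genotype_id = rep(sprintf("g%02d", 1:50), each = 2),
                  environment = "E1", trait = "t", tree_id = 1:n,
                  value = rep(rnorm(50, 0, 2), each = 2) + rnorm(n, 0, 1))
  d2 <- rbind(d, d)
  d2$environment <- rep(c("E1", "E2"), each = n)
  d2$tree_id <- seq_len(2 * n)
  set.seed(10)
  d2$value <- d2$value + rnorm(2 * n, 0, 0.5)
  target <- 37
  d2$value[target] <- d2$value[target] + 10 * sd(d2$value)
  fit <- fit_mixed_model(d2, "t")
  flags <- detect_outliers(fit)
  expect_true(target %in% flags)
  expect_length(detect_outliers(fit, alpha = 0), 0)

  # identical residuals: MAD = 0 handled, nothing flagged
  toy <- balanced_toy()
  toy$value <- rep(c(1, 2, 3), each = 2) # residuals all equal in magnitude
  fit0 <- fit_mixed_model(toy, "t")
  expect_length(detect_outliers(fit0), 0)
})

test_that("variance decomposition evaluates the clonal-mean formula and limits", {
  eq <- clonal_mean_h2(3, 2, 4, 2, 2)
  expect_identical(eq$var_p, 5)
  expect_identical(eq$h2, 0.6)
  expect_equal(clonal_mean_h2(3, 0, 0, 2, 2)$h2, 1)
  expect_equal(clonal_mean_h2(0, 2, 4, 2, 2)$h2, 0)
  expect_error(clonal_mean_h2(3, 2, 4, 0, 2), "positive")

  toy <- balanced_toy()
  fit <- fit_mixed_model(toy, "t")
  vd <- variance_decomposition(fit)
  expect_equal(vd$n_e, 1)
  expect_equal(vd$nr_bar, 2)
  expect_equal(vd$h2, 3 / (3 + 2 / 2), tolerance = 1e-6)
  expect_true(all(vd$proportions >= 0 & vd$proportions <= 1))
})

test_that("clonal values are centered, order-invariant and unshrunk without noise", {
  toy <- balanced_toy()
  fit1 <- fit_mixed_model(toy, "t")
  shuffled <- toy[sample(nrow(toy)), ]
  fit2 <- fit_mixed_model(shuffled, "t")
  expect_equal(clonal_values(fit1), clonal_values(fit2), tolerance = 1e-8)

  # near-zero residual variance: BLUPs approach genotype means - fixed effect
  lownoise <- toy
  lownoise$value <- rep(c(4, 8, 6), each = 2) + c(-1, 1) * 1e-4
  fitl <- fit_mixed_model(lownoise, "t")
  cv <- clonal_values(fitl)
  expect_equal(unname(cv[c("g1", "g2", "g3")]), c(-2, 2, 0),
               tolerance = 1e-3)
})
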