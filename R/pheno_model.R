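#' @importFrom lme4 lmer lmerControl VarCorr ranef isSingular .makeCC
NULL

# tightened optimizer tolerances so REML reproduces balanced-design ANOVA
# closed forms to well below 1e-6
lmer_ctl <- function() {
  lme4::lmerControl(
    optimizer = "nloptwrap",
    optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-14),
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    calc.derivs = FALSE)
}

check_records <- function(records) {
  req <- c("genotype_id", "environment", "trait", "value")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("phenotype records lack column(s): ",
                         paste(miss, collapse = ", "))
  invisible(records)
}

varcomp_of <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  get <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  c(g = get("genotype_id"),
    ge = get("genotype_id:environment"),
    e = get("Residual"))
}

#' Fit the multi-environment clonal mixed model by REML
#'
#' Fits `value ~ environment + (1 | genotype) + (1 | genotype:environment)`
#' (fixed environment effect, random genotype and genotype-by-environment
#' effects) for one trait. With a single environment the model reduces to a
#' random genotype effect only. If the interaction variance collapses
#' (singular fit, declared when `lme4::isSingular()` or when the estimated
#' interaction share of total variance falls below 1e-6), the term is
#' dropped and the model refit.
#'
#' @param records long-format phenotype records (columns `genotype_id`,
#'   `environment`, `trait`, `value`, optionally `tree_age`).
#' @param trait trait name to model.
#' @param include_age add a linear fixed effect of tree age.
#' @return an object of class `pheno_fit`: the lme4 model plus variance
#'   components (`varcomp`), `singular_fit` flag, environment count and the
#'   records used.
#' @export
fit_mixed_model <- function(records, trait, include_age = FALSE) {
  check_records(records)
  d <- records[records$trait == trait & !is.na(records$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no records for trait ", trait)
  if (stats::sd(d$value) == 0)
    stop("zero-variance response for trait ", trait)
  d$genotype_id <- factor(d$genotype_id)
  d$environment <- factor(d$environment)
  n_env <- nlevels(d$environment)
  fixed <- if (n_env >= 2) "environment" else "1"
  if (include_age) {
    if (!"tree_age" %in% names(d) || all(is.na(d$tree_age)))
      stop("include_age = TRUE but records carry no tree_age")
    fixed <- paste(fixed, "+ tree_age")
  }
  # unestimable (aliased) fixed effects are reported by name up front
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed)), d)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("confounded fixed-effect levels: ", paste(aliased, collapse = ", "))
  }
  rand <- if (n_env >= 2) "(1 | genotype_id) + (1 | genotype_id:environment)"
          else "(1 | genotype_id)"
  form <- stats::as.formula(paste("value ~", fixed, "+", rand))
  model <- suppressMessages(
    lme4::lmer(form, data = d, REML = TRUE, control = lmer_ctl()))
  vc <- varcomp_of(model)
  singular <- FALSE
  if (n_env >= 2) {
    tot <- sum(vc)
    if (lme4::isSingular(model) || (tot > 0 && vc[["ge"]] / tot < 1e-6)) {
      singular <- TRUE
      form2 <- stats::as.formula(paste("value ~", fixed, "+ (1 | genotype_id)"))
      model <- suppressMessages(
        lme4::lmer(form2, data = d, REML = TRUE, control = lmer_ctl()))
      vc <- varcomp_of(model)
    }
  }
  structure(list(model = model, trait = trait, varcomp = vc,
                 singular_fit = singular, n_env = n_env,
                 include_age = include_age, records = d),
            class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat(sprintf(
    "<pheno_fit '%s'> %d records, %d environments%s\n  var(g)=%.4g var(ge)=%.4g var(e)=%.4g\n",
    x$trait, nrow(x$records), x$n_env,
    if (x$singular_fit) " [singular: GxE dropped]" else "",
    x$varcomp[["g"]], x$varcomp[["ge"]], x$varcomp[["e"]]))
  invisible(x)
}

#' Extract clonal values (genotype BLUPs)
#'
#' Conditional means of the random genotype effect, centered by
#' construction; these are the responses used by the prediction models.
#'
#' @param fit a [fit_mixed_model()] result.
#' @return named numeric vector of BLUPs keyed by genotype ID.
#' @export
clonal_values <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  re <- lme4::ranef(fit$model)$genotype_id
  stats::setNames(re[["(Intercept)"]], rownames(re))
}

#' Clonal mean heritability from variance components
#'
#' `H2 = var_g / (var_g + var_ge / n_e + var_e / (n_e * nr_bar))`, the
#' across-environment clonal mean heritability given the number of
#' environments and the mean number of clonal replicates per genotype and
#' environment.
#'
#' @param var_g,var_ge,var_e variance components (trait units squared).
#' @param n_e number of environments.
#' @param nr_bar mean number of genotype replications.
#' @return list with `var_p` (phenotypic variance of a clonal mean) and `h2`.
#' @export
clonal_mean_h2 <- function(var_g, var_ge, var_e, n_e, nr_bar) {
  if (n_e <= 0 || nr_bar <= 0) stop("n_e and nr_bar must be positive")
  if (any(c(var_g, var_ge, var_e) < 0)) stop("variances must be >= 0")
  var_p <- var_g + var_ge / n_e + var_e / (n_e * nr_bar)
  h2 <- if (var_p == 0) 0 else var_g / var_p
  list(var_p = var_p, h2 = h2)
}

#' Environment-specific clonal mean heritability
#'
#' One-way random-effects REML within a single environment;
#' `H2 = var_g / (var_g + var_e / nr_bar)` with `nr_bar` the mean replicate
#' count per genotype in that environment.
#'
#' @param records phenotype records.
#' @param trait trait name.
#' @param environment environment label.
#' @return heritability in \[0, 1\].
#' @export
env_specific_heritability <- function(records, trait, environment) {
  check_records(records)
  d <- records[records$trait == trait & records$environment == environment &
                 !is.na(records$value), , drop = FALSE]
  if (length(unique(d$genotype_id)) < 2)
    stop("need >= 2 genotypes in environment ", environment)
  nr_bar <- mean(table(d$genotype_id))
  if (stats::sd(d$value) == 0) return(0)
  gm <- tapply(d$value, d$genotype_id, mean)
  within_ss <- sum((d$value - gm[as.character(d$genotype_id)])^2)
  if (within_ss < 1e-12 * stats::var(d$value) * nrow(d)) return(1)
  f <- suppressMessages(lme4::lmer(value ~ 1 + (1 | genotype_id), data = d,
                                   REML = TRUE, control = lmer_ctl()))
  vc <- varcomp_of(f)
  h2 <- clonal_mean_h2(vc[["g"]], 0, vc[["e"]], 1, nr_bar)$h2
  min(max(h2, 0), 1)
}

#' Drop trait-environment combinations with poor heritability
#'
#' Removes all records of trait-environment combinations whose
#' environment-specific clonal mean heritability is strictly below
#' `threshold`. Combinations where heritability is not computable (fewer
#' than two genotypes) are retained and reported as `NA`.
#'
#' @param records phenotype records.
#' @param threshold heritability cut-off (default 0.1).
#' @return records retained, with attribute `"report"`: a data.frame of
#'   trait, environment, heritability and the drop decision.
#' @export
filter_trait_environments <- function(records, threshold = 0.1) {
  check_records(records)
  combos <- unique(records[, c("trait", "environment")])
  combos$h2 <- NA_real_
  combos$dropped <- FALSE
  for (i in seq_len(nrow(combos))) {
    h <- tryCatch(
      env_specific_heritability(records, combos$trait[i], combos$environment[i]),
      error = function(e) NA_real_)
    combos$h2[i] <- h
    combos$dropped[i] <- !is.na(h) && h < threshold
  }
  drop_key <- paste(combos$trait, combos$environment)[combos$dropped]
  keep <- !(paste(records$trait, records$environment) %in% drop_key)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- combos
  out
}

#' Flag outlying records from a fitted clonal model
#'
#' Standardizes conditional residuals by 1.4826 times the median absolute
#' deviation and flags records whose Bonferroni-Holm-adjusted two-sided
#' normal p-value falls below `alpha`. When the MAD is zero (all residuals
#' identical) nothing is flagged. Callers remove the flagged records and
#' refit.
#'
#' @param fit a [fit_mixed_model()] result.
#' @param alpha family-wise significance level (default 0.05).
#' @return integer row indices (into `fit$records`) of flagged records.
#' @export
detect_outliers <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "pheno_fit"))
  r <- stats::residuals(fit$model)
  med <- stats::median(r)
  madc <- 1.4826 * stats::median(abs(r - med))
  if (madc == 0 || alpha <= 0) return(integer(0))
  z <- (r - med) / madc
  p <- 2 * stats::pnorm(-abs(z))
  which(stats::p.adjust(p, method = "holm") < alpha)
}

#' Refit a clonal model after outlier removal
#'
#' Convenience wrapper: fit, flag outliers, drop them, refit.
#'
#' @inheritParams fit_mixed_model
#' @param alpha outlier significance level passed to [detect_outliers()].
#' @return a `pheno_fit` on the cleaned records; attribute `"n_outliers"`
#'   records how many were removed.
#' @export
fit_cleaned_model <- function(records, trait, include_age = FALSE,
                              alpha = 0.05) {
  fit <- fit_mixed_model(records, trait, include_age)
  out <- detect_outliers(fit, alpha)
  if (length(out)) {
    kept <- fit$records[-out, , drop = FALSE]
    fit <- fit_mixed_model(kept, trait, include_age)
  }
  attr(fit, "n_outliers") <- length(out)
  fit
}

#' Variance decomposition and clonal mean heritability of a fit
#'
#' Evaluates the clonal-mean phenotypic variance
#' `var_p = var_g + var_ge / n_e + var_e / (n_e * nr_bar)`, the heritability
#' `H2 = var_g / var_p`, the fixed-effect variance (variance of the fitted
#' values with all random effects set to zero) and each component's share
#' of the total.
#'
#' @param fit a [fit_mixed_model()] result.
#' @return list with the variance components, `n_e`, `nr_bar`, `var_p`,
#'   `h2`, `fixed_var`, and `proportions` over (fixed, g, ge, e).
#' @export
variance_decomposition <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  d <- fit$records
  n_e <- fit$n_env
  if (n_e == 0) stop("no environments in fit")
  cell <- table(d$genotype_id, d$environment)
  nr_bar <- mean(cell[cell > 0])
  if (nr_bar == 0) stop("no replicates in fit")
  vc <- fit$varcomp
  cm <- clonal_mean_h2(vc[["g"]], vc[["ge"]], vc[["e"]], n_e, nr_bar)
  fixed_pred <- stats::predict(fit$model, re.form = NA)
  fixed_var <- stats::var(fixed_pred)
  total <- fixed_var + sum(vc)
  props <- c(fixed = fixed_var, vc) / total
  list(var_g = vc[["g"]], var_ge = vc[["ge"]], var_e = vc[["e"]],
       n_e = n_e, nr_bar = nr_bar, var_p = cm$var_p, h2 = cm$h2,
       fixed_var = fixed_var, proportions = props,
       singular_fit = fit$singular_fit)
}
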