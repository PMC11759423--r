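#' Gibbs sampler settings for the kernel model
#'
#' Defaults are the settings used throughout the analyses: 12,000
#' iterations, burn-in of 2,000 and thinning of 5.
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in discarded leading iterations.
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param df0 prior degrees of freedom of each scaled-inverse-chi-squared
#'   variance prior.
#' @param r2 prior expected share of the response variance attributed to
#'   the kernel terms jointly (split equally among kernels).
#' @param method `"gibbs"` (default) or `"blup"`; the latter skips the
#'   sampler and returns the closed-form BLUP at REML variances.
#' @param ess_warning warn when the effective sample size of the variance
#'   ratio falls below 30 (disable for deliberately short exploratory
#'   chains).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(iterations = 12000, burn_in = 2000, thinning = 5,
                           seed = NULL, df0 = 5, r2 = 0.5,
                           method = c("gibbs", "blup"),
                           ess_warning = TRUE) {
  if (burn_in >= iterations) stop("burn_in must be below iterations")
  if (thinning < 1) stop("thinning must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = seed,
                 df0 = df0, r2 = r2, method = match.arg(method),
                 ess_warning = isTRUE(ess_warning)),
            class = "sampler_config")
}

as_kernel_list <- function(kernels) {
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  if (!length(kernels) || length(kernels) > 2)
    stop("supply one or two kernels")
  if (is.null(names(kernels)))
    names(kernels) <- vapply(kernels, function(k)
      attr(k, "source") %||% "K", "")
  names(kernels) <- make.unique(names(kernels))
  ids <- kernel_ids(kernels[[1]])
  for (k in kernels)
    if (!identical(kernel_ids(k), ids))
      stop("kernels must be aligned on the same individual IDs in the same order")
  kernels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

align_response <- function(kernels, y) {
  ids <- kernel_ids(kernels[[1]])
  if (is.null(names(y))) {
    if (length(y) != length(ids))
      stop("unnamed response must match kernel dimension")
    names(y) <- ids
  }
  extra <- setdiff(names(y), ids)
  if (length(extra))
    stop("response IDs missing from kernel: ", paste(utils::head(extra, 5),
                                                     collapse = ", "))
  full <- stats::setNames(rep(NA_real_, length(ids)), ids)
  full[names(y)] <- y
  if (!any(!is.na(full))) stop("all responses are masked")
  full
}

# eigen-decomposition of a kernel keeping numerically positive components;
# returns B with B %*% t(B) = K (up to dropped null space)
kernel_root <- function(K, tol = 1e-8) {
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 1)
  B <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                sum(keep))
  list(B = B, d = e$values[keep])
}

#' Fit the single- or two-kernel model by Gibbs sampling
#'
#' Bayesian kernel regression `y = 1 mu + u_1 (+ u_2) + e` with
#' `u_k ~ N(0, K_k s2_k)` and `e ~ N(0, I s2_e)` (the RKHS equivalent of
#' G-BLUP; the combined model sums two independent kernel effects).
#' Variances carry scaled-inverse-chi-squared priors; masked responses are
#' imputed by data augmentation each iteration, so every individual in the
#' kernel receives a prediction. Posterior means are reported.
#'
#' @param kernels a [kernel_matrix()] or (named) list of one or two,
#'   aligned on the same IDs.
#' @param y named numeric responses; `NA` marks masked (validation)
#'   entries. IDs present in the kernel but absent from `y` are masked.
#' @param config a [sampler_config()]. With `method = "blup"` the
#'   closed-form oracle at REML variances is returned instead.
#' @return an object of class `kernel_fit`: posterior-mean predictions
#'   `yhat` (`mu + sum(u)`), per-kernel effects `u`, variance estimates
#'   `var_u` and `var_e`, posterior samples of the variance ratio, and the
#'   settings used.
#' @export
fit_kernel_model <- function(kernels, y, config = sampler_config()) {
  kernels <- as_kernel_list(kernels)
  yfull <- align_response(kernels, y)
  if (config$method == "blup") {
    vc <- kernel_reml(kernels, yfull)
    fit <- blup_oracle(kernels, yfull, vc$var_u, vc$var_e)
    return(structure(list(yhat = fit$yhat, mu = fit$mu, u = fit$u,
                          var_u = vc$var_u, var_e = vc$var_e,
                          ratio_samples = NULL, settings = config,
                          ids = names(yfull), masked = is.na(yfull)),
                     class = "kernel_fit"))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(yfull)
  obs <- !is.na(yfull)
  vy <- stats::var(yfull[obs])
  if (!is.finite(vy) || vy == 0) vy <- 1
  nk <- length(kernels)
  roots <- lapply(kernels, kernel_root)
  df0 <- config$df0
  # prior scales: E[s2] = df0*S/(df0-2) matched to the prior variance split
  S_u <- (config$r2 * vy / nk) * (df0 - 2) / df0
  S_e <- ((1 - config$r2) * vy) * (df0 - 2) / df0
  mu <- mean(yfull[obs])
  delta <- lapply(roots, function(r) rep(0, length(r$d)))
  u <- lapply(roots, function(r) rep(0, n))
  s2_u <- rep(config$r2 * vy / nk, nk)
  s2_e <- (1 - config$r2) * vy
  ycur <- yfull
  ycur[!obs] <- mu
  keep <- seq(config$burn_in + 1, config$iterations) # thinned below
  keep <- keep[(keep - config$burn_in) %% config$thinning == 0]
  acc_yhat <- rep(0, n)
  acc_u <- lapply(seq_len(nk), function(i) rep(0, n))
  acc_s2u <- rep(0, nk); acc_s2e <- 0
  ratio_samples <- numeric(length(keep))
  kept <- 0L
  for (it in seq_len(config$iterations)) {
    eta <- mu + Reduce(`+`, u)
    # data augmentation for masked responses
    if (any(!obs))
      ycur[!obs] <- eta[!obs] + stats::rnorm(sum(!obs), 0, sqrt(s2_e))
    # intercept
    resid_no_mu <- ycur - Reduce(`+`, u)
    mu <- stats::rnorm(1, mean(resid_no_mu), sqrt(s2_e / n))
    # kernel effects in the eigenbasis: conditional posteriors are
    # independent because t(B) %*% B = diag(d)
    for (k in seq_len(nk)) {
      ek <- ycur - mu - Reduce(`+`, u[-k], accumulate = FALSE,
                               init = rep(0, n))
      r <- crossprod(roots[[k]]$B, ek)
      prec <- roots[[k]]$d / s2_e + 1 / s2_u[k]
      mean_d <- (r / s2_e) / prec
      delta[[k]] <- drop(mean_d) + stats::rnorm(length(prec)) / sqrt(prec)
      u[[k]] <- drop(roots[[k]]$B %*% delta[[k]])
      ss <- sum(delta[[k]]^2)
      s2_u[k] <- (df0 * S_u + ss) / stats::rchisq(1, df0 + length(delta[[k]]))
    }
    ee <- ycur - mu - Reduce(`+`, u)
    s2_e <- (df0 * S_e + sum(ee^2)) / stats::rchisq(1, df0 + n)
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thinning == 0) {
      kept <- kept + 1L
      acc_yhat <- acc_yhat + mu + Reduce(`+`, u)
      for (k in seq_len(nk)) acc_u[[k]] <- acc_u[[k]] + u[[k]]
      acc_s2u <- acc_s2u + s2_u
      acc_s2e <- acc_s2e + s2_e
      ratio_samples[kept] <- sum(s2_u) / (sum(s2_u) + s2_e)
    }
  }
  ids <- names(yfull)
  yhat <- stats::setNames(acc_yhat / kept, ids)
  u_mean <- lapply(acc_u, function(a) stats::setNames(a / kept, ids))
  names(u_mean) <- names(kernels)
  var_u <- stats::setNames(acc_s2u / kept, names(kernels))
  ess <- ess_of(ratio_samples)
  if (isTRUE(config$ess_warning) && is.finite(ess) && ess < 30)
    warning("low effective sample size (", round(ess), ") for the variance ratio")
  structure(list(yhat = yhat, mu = NULL, u = u_mean, var_u = var_u,
                 var_e = acc_s2e / kept, ratio_samples = ratio_samples,
                 settings = config, ids = ids, masked = !obs,
                 ess_ratio = ess),
            class = "kernel_fit")
}

# crude autocorrelation-based effective sample size
ess_of <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- ac[seq_len(max(1, which(ac < 0)[1] - 1, na.rm = TRUE))]
  n / (1 + 2 * sum(pos, na.rm = TRUE))
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel_fit> %d individuals (%d masked), var_u = %s, var_e = %.4g\n",
              length(x$ids), sum(x$masked),
              paste(sprintf("%.4g", x$var_u), collapse = "/"), x$var_e))
  invisible(x)
}

#' Closed-form BLUP for fixed variance components
#'
#' Solves the mixed-model equations exactly for given variances:
#' `V = sum_k K_k s2_k + I s2_e` on the observed entries, generalized
#' least-squares intercept, and `u_k = s2_k K_k[, obs] V^-1 (y - mu)`
#' extended to masked entries through the kernel covariance.
#'
#' @param kernels a [kernel_matrix()] or list of one or two.
#' @param y named responses with `NA` for masked entries.
#' @param var_u numeric vector of kernel variances (> 0), one per kernel.
#' @param var_e residual variance (> 0).
#' @return list with `mu`, `u` (list per kernel, full length) and `yhat`.
#' @export
blup_oracle <- function(kernels, y, var_u, var_e) {
  kernels <- as_kernel_list(kernels)
  yfull <- align_response(kernels, y)
  if (length(var_u) != length(kernels))
    stop("one variance per kernel required")
  if (any(var_u < 0) || var_e <= 0) stop("variances must be positive")
  obs <- !is.na(yfull)
  n <- length(yfull)
  Vo <- diag(var_e, sum(obs))
  for (k in seq_along(kernels))
    Vo <- Vo + var_u[k] * kernels[[k]][obs, obs, drop = FALSE]
  Vi <- tryCatch(solve(Vo), error = function(e)
    stop("singular mixed-model system: ", conditionMessage(e)))
  one <- rep(1, sum(obs))
  mu <- drop(crossprod(one, Vi %*% yfull[obs]) / crossprod(one, Vi %*% one))
  alpha <- Vi %*% (yfull[obs] - mu)
  u <- lapply(seq_along(kernels), function(k)
    stats::setNames(drop(var_u[k] * kernels[[k]][, obs, drop = FALSE] %*% alpha),
                    names(yfull)))
  names(u) <- names(kernels)
  yhat <- mu + Reduce(`+`, u)
  list(mu = mu, u = u, yhat = yhat)
}

#' REML variance components for the kernel model
#'
#' Profiled REML over the variance ratio(s) using the eigen-rotation of the
#' observed-block kernel(s); one-dimensional `optimize` for a single
#' kernel, `optim` on log-ratios for two. Used as the independent
#' cross-check of the Gibbs sampler and by the fast `method = "blup"` path.
#'
#' @param kernels a [kernel_matrix()] or list of one or two.
#' @param y named responses with `NA` for masked entries.
#' @return list with `var_u` (vector) and `var_e`.
#' @export
kernel_reml <- function(kernels, y) {
  kernels <- as_kernel_list(kernels)
  yfull <- align_response(kernels, y)
  obs <- !is.na(yfull)
  yo <- yfull[obs]
  n <- length(yo)
  Ko <- lapply(kernels, function(k) k[obs, obs, drop = FALSE])
  X <- matrix(1, n, 1)
  reml_dev <- function(log_phi) {
    phi <- exp(log_phi)
    V0 <- diag(1, n)
    for (k in seq_along(Ko)) V0 <- V0 + phi[k] * Ko[[k]]
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), yo))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(Vi_X, yo))
    r <- yo - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    q <- drop(crossprod(r, Vi_r))
    # profiled REML deviance in the residual variance
    drop(logdetV + log(det(XtViX)) + (n - 1) * log(q))
  }
  nk <- length(Ko)
  if (nk == 1) {
    opt <- stats::optimize(function(lp) reml_dev(lp), c(-12, 12))
    phi <- exp(opt$minimum)
  } else {
    opt <- stats::optim(rep(0, nk), reml_dev, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    phi <- exp(opt$par)
  }
  V0 <- diag(1, n)
  for (k in seq_len(nk)) V0 <- V0 + phi[k] * Ko[[k]]
  Vi <- solve(V0)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% yo) / crossprod(one, Vi %*% one))
  r <- yo - mu
  s2e <- drop(crossprod(r, Vi %*% r)) / (n - 1)
  list(var_u = stats::setNames(phi * s2e, names(kernels)), var_e = s2e)
}

#' Predictive ability: Pearson correlation of observed and predicted
#'
#' Sample Pearson correlation between clonal (observed) values and model
#' predictions. With a constant vector the correlation is undefined: the
#' result is `NA` flagged with attribute `"undefined"`, which downstream
#' averaging drops and counts.
#'
#' @param observed,predicted paired numeric vectors (>= 3 pairs).
#' @return correlation coefficient, or flagged `NA` when undefined.
#' @export
predictive_ability <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  guarded_cor(observed, predicted)
}
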