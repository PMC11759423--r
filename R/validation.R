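#' Leave-one-family-out training/validation splits
#'
#' One split per validation family: the family's members form the
#' validation set and every other eligible individual the training set.
#' With `single_block = TRUE` all validation families are pooled into one
#' validation block (not a leave-one-family-out in a strict sense, but the
#' same machinery).
#'
#' @param family_map named character vector, genotype ID to family label
#'   (`"ACCESSION"` for unrelated panel members).
#' @param validation_families families to hold out (default: all families
#'   other than `"ACCESSION"`).
#' @param training_pool IDs eligible for training (default: everyone).
#' @param single_block pool all validation families into a single split.
#' @return list of splits, each `list(family, train, validation)`;
#'   attribute `"small_families"` flags families with < 2 members.
#' @export
make_lofo_splits <- function(family_map, validation_families = NULL,
                             training_pool = NULL, single_block = FALSE) {
  stopifnot(!is.null(names(family_map)))
  fams <- setdiff(unique(family_map), "ACCESSION")
  if (is.null(validation_families)) validation_families <- fams
  if (!length(validation_families)) stop("no validation families")
  if (!single_block && length(validation_families) < 2 &&
      length(fams) < 2)
    stop("need >= 2 families for leave-one-family-out")
  if (is.null(training_pool)) training_pool <- names(family_map)
  missing_fam <- setdiff(validation_families, family_map)
  if (length(missing_fam))
    stop("unknown families: ", paste(missing_fam, collapse = ", "))
  small <- validation_families[vapply(validation_families, function(f)
    sum(family_map == f) < 2, TRUE)]
  mk <- function(fam_set, label) {
    val <- names(family_map)[family_map %in% fam_set]
    train <- setdiff(training_pool, val)
    if (!length(train)) stop("empty training set for ", label)
    list(family = label, train = train, validation = val)
  }
  splits <- if (single_block) {
    list(mk(validation_families, "single_block"))
  } else {
    lapply(validation_families, function(f) mk(f, f))
  }
  attr(splits, "small_families") <- small
  splits
}

#' Repeated k-fold cross-validation assignments
#'
#' Random partitions without replacement; per repeat, fold sizes differ by
#' at most one.
#'
#' @param ids genotype IDs.
#' @param k number of folds (>= 2).
#' @param repeats number of repetitions.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `rep`, `fold`.
#' @export
make_cv_folds <- function(ids, k = 10, repeats = 10, seed = NULL) {
  n <- length(ids)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_len(repeats), function(r) {
    data.frame(id = ids, rep = r,
               fold = sample(rep(seq_len(k), length.out = n)))
  }))
}

#' Per-family predictive abilities (LOFO1)
#'
#' @param predictions data.frame with columns `family`, `observed`,
#'   `predicted`.
#' @return data.frame of `family`, `n`, `ability` (`NA` when undefined,
#'   e.g. a constant family).
#' @export
ability_lofo1 <- function(predictions) {
  stopifnot(all(c("family", "observed", "predicted") %in% names(predictions)))
  fams <- unique(predictions$family)
  out <- lapply(fams, function(f) {
    d <- predictions[predictions$family == f, ]
    r <- tryCatch(predictive_ability(d$observed, d$predicted),
                  error = function(e) NA_real_)
    data.frame(family = f, n = nrow(d), ability = as.numeric(r))
  })
  do.call(rbind, out)
}

#' Pooled predictive ability across validation families (LOFO2)
#'
#' @param predictions data.frame with columns `observed`, `predicted`.
#' @return single Pearson correlation over all pooled pairs.
#' @export
ability_lofo2 <- function(predictions) {
  stopifnot(all(c("observed", "predicted") %in% names(predictions)))
  as.numeric(predictive_ability(predictions$observed, predictions$predicted))
}

#' Per-repeat predictive abilities for k-fold cross-validation
#'
#' @param predictions data.frame with columns `id`, `rep`, `observed`,
#'   `predicted`.
#' @param target_ids optional subset of IDs on which ability is assessed
#'   (e.g. members of specific validation families).
#' @return data.frame of `rep`, `n`, `ability`.
#' @export
ability_cv <- function(predictions, target_ids = NULL) {
  stopifnot(all(c("id", "rep", "observed", "predicted") %in%
                  names(predictions)))
  reps <- sort(unique(predictions$rep))
  out <- lapply(reps, function(r) {
    d <- predictions[predictions$rep == r, ]
    if (anyDuplicated(d$id))
      stop("id predicted more than once in repeat ", r)
    if (!is.null(target_ids)) d <- d[d$id %in% target_ids, ]
    ab <- tryCatch(predictive_ability(d$observed, d$predicted),
                   error = function(e) NA_real_)
    data.frame(rep = r, n = nrow(d), ability = as.numeric(ab))
  })
  do.call(rbind, out)
}

#' Declare a prediction scenario
#'
#' A scenario names the kernel(s), the validation scheme, the training-set
#' composition and the traits to run; [run_scenario_grid()] executes lists
#' of these.
#'
#' @param id scenario label.
#' @param kernels character vector of kernel names (length 1 or 2; two
#'   names request the combined two-kernel model).
#' @param scheme `"LOFO"` (computes both the per-family and the pooled
#'   ability), `"single_block"` or `"CV"`.
#' @param training_pool IDs eligible for training (`NULL` = everyone).
#' @param validation_families families to hold out (LOFO / single_block).
#' @param cv_ids IDs entering cross-validation (`NULL` = everyone with a
#'   response).
#' @param cv_target_families optional families on whose members the CV
#'   ability is assessed (everyone is still predicted); keeps scheme
#'   comparisons on identical genotype sets.
#' @param k,repeats fold count and repetitions for CV.
#' @param traits traits to run (`NULL` = all responses).
#' @param seed integer seed for fold assignment and the sampler.
#' @return a `scenario` list.
#' @export
scenario <- function(id, kernels = "G", scheme = c("LOFO", "single_block", "CV"),
                     training_pool = NULL, validation_families = NULL,
                     cv_ids = NULL, cv_target_families = NULL, k = 10,
                     repeats = 10, traits = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  if (!length(kernels) || length(kernels) > 2)
    stop("a scenario uses one or two kernels")
  if (scheme == "CV" && k < 2) stop("CV requires k >= 2")
  structure(list(id = id, kernels = kernels, scheme = scheme,
                 training_pool = training_pool,
                 validation_families = validation_families,
                 cv_ids = cv_ids, cv_target_families = cv_target_families,
                 k = k, repeats = repeats, traits = traits, seed = seed),
            class = "scenario")
}

# mask validation entries and verify no leakage into the training responses
masked_response <- function(y, validation_ids) {
  ym <- y
  ym[names(ym) %in% validation_ids] <- NA
  if (any(names(ym)[!is.na(ym)] %in% validation_ids))
    stop("internal leakage check failed")
  ym
}

fit_and_predict <- function(kernels, y, validation_ids, config) {
  ym <- masked_response(y, validation_ids)
  if (!any(!is.na(ym))) stop("empty training set after masking")
  fit <- fit_kernel_model(kernels, ym, config)
  fit$yhat[validation_ids]
}

#' Run a grid of prediction scenarios
#'
#' Resolves every scenario against the supplied data (failing before any
#' model run if a kernel, trait or family cannot be found), executes the
#' requested splits and models, and returns a tidy results table of
#' predictive abilities.
#'
#' @param scenarios list of [scenario()] objects.
#' @param kernels named list of [kernel_matrix()] objects, all aligned on
#'   the same IDs.
#' @param responses named list: trait name to named numeric vector of
#'   responses (e.g. clonal values).
#' @param family_map named character vector, ID to family label.
#' @param config a [sampler_config()]; its seed is combined with each
#'   scenario's seed.
#' @return data.frame with columns `scenario_id`, `trait`, `scheme`,
#'   `validation_unit`, `ability`, `n_pairs`; attribute `"diagnostics"`
#'   counts undefined correlations per scenario.
#' @export
run_scenario_grid <- function(scenarios, kernels, responses, family_map,
                              config = sampler_config()) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  # resolve everything first: fail before any model run
  for (sc in scenarios) {
    missing_k <- setdiff(sc$kernels, names(kernels))
    if (length(missing_k))
      stop("scenario ", sc$id, ": unknown kernel(s) ",
           paste(missing_k, collapse = ", "))
    tr <- sc$traits %||% names(responses)
    missing_t <- setdiff(tr, names(responses))
    if (length(missing_t))
      stop("scenario ", sc$id, ": unknown trait(s) ",
           paste(missing_t, collapse = ", "))
    bad <- setdiff(c(sc$validation_families, sc$cv_target_families),
                   family_map)
    if (length(bad))
      stop("scenario ", sc$id, ": unknown families ",
           paste(bad, collapse = ", "))
  }
  rows <- list()
  undefined <- stats::setNames(integer(length(scenarios)),
                               vapply(scenarios, `[[`, "", "id"))
  for (sc in scenarios) {
    klist <- kernels[sc$kernels]
    traits <- sc$traits %||% names(responses)
    for (trait in traits) {
      y <- responses[[trait]]
      cfg <- config
      cfg$seed <- if (is.null(config$seed)) sc$seed else config$seed + sc$seed
      if (sc$scheme %in% c("LOFO", "single_block")) {
        splits <- make_lofo_splits(family_map,
                                   validation_families = sc$validation_families,
                                   training_pool = sc$training_pool,
                                   single_block = sc$scheme == "single_block")
        preds <- do.call(rbind, lapply(splits, function(sp) {
          val <- intersect(sp$validation, names(y))
          ytr <- y[intersect(names(y), c(sp$train, val))]
          ph <- fit_and_predict(klist, ytr, val, cfg)
          data.frame(id = val, family = unname(family_map[val]),
                     observed = unname(y[val]), predicted = unname(ph))
        }))
        l1 <- ability_lofo1(preds)
        undefined[sc$id] <- undefined[sc$id] + sum(is.na(l1$ability))
        rows[[length(rows) + 1]] <- data.frame(
          scenario_id = sc$id, trait = trait, scheme = "LOFO1",
          validation_unit = l1$family, ability = l1$ability, n_pairs = l1$n)
        l2 <- ability_lofo2(preds)
        rows[[length(rows) + 1]] <- data.frame(
          scenario_id = sc$id, trait = trait, scheme = "LOFO2",
          validation_unit = "pooled", ability = l2, n_pairs = nrow(preds))
      } else {
        ids <- sc$cv_ids %||% names(y)
        folds <- make_cv_folds(ids, k = sc$k, repeats = sc$repeats,
                               seed = cfg$seed)
        preds <- do.call(rbind, lapply(unique(folds$rep), function(r) {
          fr <- folds[folds$rep == r, ]
          do.call(rbind, lapply(seq_len(sc$k), function(f) {
            val <- fr$id[fr$fold == f]
            ph <- fit_and_predict(klist, y[ids], val, cfg)
            data.frame(id = val, rep = r, observed = unname(y[val]),
                       predicted = unname(ph))
          }))
        }))
        target <- if (is.null(sc$cv_target_families)) NULL
                  else names(family_map)[family_map %in%
                                           sc$cv_target_families]
        ab <- ability_cv(preds, target_ids = target)
        undefined[sc$id] <- undefined[sc$id] + sum(is.na(ab$ability))
        rows[[length(rows) + 1]] <- data.frame(
          scenario_id = sc$id, trait = trait, scheme = "CV",
          validation_unit = sprintf("rep%02d", ab$rep), ability = ab$ability,
          n_pairs = ab$n)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- data.frame(scenario_id = names(undefined),
                                         undefined = unname(undefined))
  out
}

#' Average abilities across traits and validation units
#'
#' Across-trait averages drop flagged undefined abilities and report how
#' many were dropped.
#'
#' @param results a [run_scenario_grid()] table.
#' @return data.frame of `scenario_id`, `scheme`, `mean_ability`,
#'   `n_values`, `n_dropped`.
#' @export
summarize_abilities <- function(results) {
  key <- interaction(results$scenario_id, results$scheme, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    d <- results[key == k, ]
    data.frame(scenario_id = d$scenario_id[1], scheme = d$scheme[1],
               mean_ability = mean(d$ability, na.rm = TRUE),
               n_values = sum(!is.na(d$ability)),
               n_dropped = sum(is.na(d$ability)))
  })
  do.call(rbind, out)
}
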