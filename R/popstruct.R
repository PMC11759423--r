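#' Principal component analysis of genotype dosages
#'
#' PCA on column-centered dosages (missing values mean-filled), with the
#' percentage of variance explained per component.
#'
#' @param genotypes a [genotype_matrix()] or plain numeric matrix.
#' @param n_components number of components to return.
#' @return list with `scores` (individuals x components), `percent_var`
#'   and `sdev`.
#' @export
genotype_pca <- function(genotypes, n_components = 10) {
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages
       else as.matrix(genotypes)
  if (nrow(X) < 2) stop("need >= 2 individuals")
  if (anyNA(X)) {
    fill <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- fill[idx[, 2]]
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) stop("degenerate input: no variance")
  pc <- stats::prcomp(Xc, center = FALSE)
  k <- min(n_components, ncol(pc$x))
  pvar <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       percent_var = pvar[seq_len(k)], sdev = pc$sdev)
}

#' Identity-by-state similarity and distance
#'
#' Per-SNP IBS between two dosages is `1 - |d1 - d2| / 2` (1, 0.5, 0 for
#' dosage pairs differing by 0, 1, 2), averaged over SNPs. The genetic
#' distance is one minus the similarity. Missing dosages are mean-filled.
#'
#' @param genotypes a [genotype_matrix()] or numeric matrix.
#' @return a [kernel_matrix()] of IBS similarities with attribute
#'   `"distance"` holding the distance matrix.
#' @export
ibs_matrix <- function(genotypes) {
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages
       else as.matrix(genotypes)
  if (anyNA(X)) {
    fill <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- fill[idx[, 2]]
  }
  D <- as.matrix(stats::dist(X, method = "manhattan")) / (2 * ncol(X))
  ibs <- 1 - D
  k <- kernel_matrix(ibs, source = "IBS")
  attr(k, "distance") <- D
  k
}

#' Parallel analysis for the number of significant components
#'
#' Modified Horn procedure: components are retained while the observed
#' eigenvalue of the correlation matrix exceeds the `(1 - alpha)` quantile
#' of eigenvalues obtained from replicates with independently permuted
#' columns (which preserves the marginal distributions and breaks the
#' correlation structure).
#'
#' @param x numeric matrix (observations x variables); constant columns
#'   are dropped.
#' @param iterations number of permutation replicates (default 10000;
#'   reduce for quick runs).
#' @param alpha significance level of the null quantile (default 0.01).
#' @param seed integer seed.
#' @return list with `k` (retained components), `observed` eigenvalues and
#'   the null `threshold` per component.
#' @export
parallel_analysis <- function(x, iterations = 10000, alpha = 0.01,
                              seed = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 columns")
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 2) stop("fewer than 2 non-constant columns")
  if (!is.null(seed)) set.seed(seed)
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  p <- ncol(x)
  null_eig <- matrix(0, iterations, p)
  for (i in seq_len(iterations)) {
    perm <- apply(x, 2, sample)
    null_eig[i, ] <- eigen(stats::cor(perm), symmetric = TRUE,
                           only.values = TRUE)$values
  }
  thr <- apply(null_eig, 2, stats::quantile, probs = 1 - alpha)
  exceeds <- obs > thr
  k <- if (all(exceeds)) p else which(!exceeds)[1] - 1L
  list(k = as.integer(k), observed = obs, threshold = thr)
}

#' Genetic contribution scores from a relationship matrix
#'
#' Eigen-decomposes a symmetric relationship matrix and scores each
#' individual as the eigenvalue-weighted sum of absolute correlations
#' between its relationship row and the first `k` eigenvectors:
#' `gc_j = sum_i w_i |cor(a_j, v_i)|` with `w_i = lambda_i / sum(lambda)`
#' over the retained components. Scores lie in \[0, 1\].
#'
#' @param relationship a symmetric relationship matrix (e.g. IBS or GRM).
#' @param k number of significant components, typically from
#'   [parallel_analysis()].
#' @return named numeric vector of scores.
#' @export
genetic_contribution_scores <- function(relationship, k) {
  K <- as.matrix(relationship)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8)
    stop("relationship matrix must be symmetric")
  n <- nrow(K)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  if (sum(lam) == 0) stop("no positive eigenvalues among the first k")
  w <- lam / sum(lam)
  gc <- vapply(seq_len(n), function(j) {
    a <- K[j, ]
    sum(w * vapply(seq_len(k), function(i) {
      v <- e$vectors[, i]
      # near-constant vectors (e.g. the leading eigenvector of an
      # equicorrelated matrix) make the correlation undefined
      if (stats::sd(a) < 1e-12 || stats::sd(v) < 1e-12) 0
      else abs(stats::cor(a, v))
    }, 0))
  }, 0)
  stats::setNames(gc, rownames(K))
}

#' Mutual k-nearest-neighbour population network
#'
#' Links every genotype to its `k` nearest neighbours by genetic distance
#' (union of directed choices, undirected edges; ties broken by stable ID
#' order). Node attributes carry genetic contribution scores and group
#' labels when supplied.
#'
#' @param distance square symmetric distance matrix with IDs as dimnames.
#' @param k neighbours per node (`k < n`), default 30.
#' @param gc optional named numeric node scores.
#' @param groups optional named character node labels.
#' @return list with `graph` (an igraph object), `edges` (data.frame of
#'   `from`, `to`, `distance`) and `k`.
#' @export
knn_network <- function(distance, k = 30, gc = NULL, groups = NULL) {
  D <- as.matrix(distance)
  n <- nrow(D)
  if (n != ncol(D)) stop("distance matrix must be square")
  if (k >= n) stop("k must be below the number of genotypes")
  ids <- rownames(D) %||% paste0("g", seq_len(n))
  rownames(D) <- colnames(D) <- ids
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- D[i, -i]
    ord <- order(d, names(d)) # stable: distance, then ID
    nb <- names(d)[ord][seq_len(k)]
    data.frame(from = ids[i], to = nb, distance = unname(d[nb]))
  }))
  # undirected union of directed choices, deduplicated
  pair <- t(apply(edges[, 1:2], 1, sort))
  keyp <- paste(pair[, 1], pair[, 2])
  edges <- data.frame(from = pair[, 1], to = pair[, 2],
                      distance = edges$distance)[!duplicated(keyp), ]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(gc)) igraph::V(g)$gc <- unname(gc[ids])
  if (!is.null(groups)) igraph::V(g)$group <- unname(groups[ids])
  list(graph = g, edges = edges, k = k)
}

#' Write a network as an edge-list TSV (and optional GraphML)
#'
#' @param network a [knn_network()] result.
#' @param path output TSV path.
#' @param graphml optional GraphML output path.
#' @return invisibly, the edge data.frame written.
#' @export
write_network <- function(network, path, graphml = NULL) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(network$graph, graphml, format = "graphml")
  invisible(network$edges)
}
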