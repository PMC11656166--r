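#' Random-forest parameters
#'
#' @param n_trees number of trees (>= 1; values below 50 give noisy
#'   proximity estimates and trigger a warning downstream).
#' @param mtry variables sampled at each split (1..n_regions).
#' @param nodesize minimum terminal-node size (>= 1; the default 5 smooths
#'   the proximity estimates relative to fully grown trees).
#' @param seed integer RNG seed.
#' @return An `rf_params` list.
#' @export
rf_params <- function(n_trees = 2000, mtry = NULL, nodesize = 5, seed = 1L) {
  stopifnot(n_trees >= 1, nodesize >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 nodesize = as.integer(nodesize), seed = as.integer(seed)),
            class = "rf_params")
}

#' Synthetic contrast sample for unsupervised random forests
#'
#' Builds the second class against which the forest discriminates the real
#' observations: each column is an independent bootstrap resample of the
#' corresponding real column, preserving every marginal distribution while
#' destroying the between-column dependence that carries the cluster
#' structure.
#'
#' @param X numeric matrix (subjects x features).
#' @param seed integer seed.
#' @return Matrix of the same shape as `X`.
#' @export
make_contrast_sample <- function(X, seed = 1L) {
  if (nrow(X) < 2) stop("need at least 2 rows")
  set.seed(seed)
  apply(X, 2, function(col) sample(col, length(col), replace = TRUE))
}

#' Unsupervised random-forest dissimilarity
#'
#' Trains a classification forest to separate the real rows from a
#' marginal-resampled contrast sample and reads off the proximity of every
#' real pair: the fraction of trees in which the two subjects fall in the
#' same terminal node. The dissimilarity is `sqrt(1 - proximity)` by
#' default (a metric-friendlier transform; set `sqrt_transform = FALSE`
#' for `1 - proximity`). Proximity is counted over all trees for all pairs
#' unless `oob_prox = TRUE`.
#'
#' @param X numeric matrix (subjects x features), complete.
#' @param params an [rf_params()].
#' @param sqrt_transform use `sqrt(1 - proximity)`.
#' @param oob_prox count proximity only over trees where both cases are
#'   out of bag.
#' @return An `rf_dissimilarity` object: `d` (n x n symmetric matrix with
#'   zero diagonal, entries in [0, 1]), `oob_error`, `params`.
#' @export
rf_dissimilarity <- function(X, params = rf_params(),
                             sqrt_transform = TRUE, oob_prox = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (params$n_trees < 50)
    warning("fewer than 50 trees gives unstable proximity estimates")
  contrast <- make_contrast_sample(X, seed = params$seed)
  set.seed(params$seed)
  mtry <- if (is.null(params$mtry)) max(1L, floor(sqrt(ncol(X))))
          else min(params$mtry, ncol(X))
  fit <- randomForest::randomForest(
    x = rbind(X, contrast),
    y = factor(rep(c("real", "contrast"), each = n)),
    ntree = params$n_trees, mtry = mtry, nodesize = params$nodesize,
    proximity = TRUE, oob.prox = oob_prox)
  prox <- fit$proximity[seq_len(n), seq_len(n)]
  d <- if (sqrt_transform) sqrt(pmax(1 - prox, 0)) else pmax(1 - prox, 0)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  structure(list(d = d,
                 oob_error = fit$err.rate[params$n_trees, "OOB"],
                 params = params),
            class = "rf_dissimilarity")
}

#' Tune mtry and nodesize by out-of-bag error
#'
#' Evaluates the out-of-bag misclassification error of the
#' real-versus-contrast forest over a grid of `mtry` and `nodesize` values
#' and returns the minimizing pair, breaking ties toward smaller `mtry`
#' then smaller `nodesize`. The same contrast sample is used for every
#' grid cell so cells are compared on identical data.
#'
#' @param X numeric matrix.
#' @param mtry_grid,nodesize_grid integer vectors (non-empty).
#' @param n_trees trees per evaluation.
#' @param seed integer seed.
#' @return An [rf_params()] with the selected values; the full grid with
#'   OOB errors is attached as attribute `"grid"`.
#' @export
tune_rf <- function(X, mtry_grid = c(5, 9, 15, 27), nodesize_grid = c(1, 5, 10),
                    n_trees = 2000, seed = 1L) {
  if (!length(mtry_grid) || !length(nodesize_grid))
    stop("grids must be non-empty")
  X <- as.matrix(X)
  mtry_grid <- sort(unique(pmin(mtry_grid, ncol(X))))
  nodesize_grid <- sort(unique(nodesize_grid))
  contrast <- make_contrast_sample(X, seed = seed)
  Xy <- rbind(X, contrast)
  y <- factor(rep(c("real", "contrast"), each = nrow(X)))
  grid <- expand.grid(mtry = mtry_grid, nodesize = nodesize_grid)
  grid$oob_error <- vapply(seq_len(nrow(grid)), function(i) {
    set.seed(seed + i)
    fit <- randomForest::randomForest(x = Xy, y = y, ntree = n_trees,
                                      mtry = grid$mtry[i],
                                      nodesize = grid$nodesize[i])
    unname(fit$err.rate[n_trees, "OOB"])
  }, numeric(1))
  ord <- order(grid$oob_error, grid$mtry, grid$nodesize)
  best <- grid[ord[1], ]
  out <- rf_params(n_trees = n_trees, mtry = best$mtry,
                   nodesize = best$nodesize, seed = seed)
  attr(out, "grid") <- grid
  out
}

#' Stability of the random-forest dissimilarity
#'
#' Re-runs the dissimilarity computation under `n_runs` distinct seeds and
#' summarizes, for each run, the element-wise absolute difference from the
#' reference matrix (the one built from `params`) and, when `k` is given,
#' the adjusted Rand index between the run's downstream cluster labels and
#' the reference labels (classical MDS to `mds_dims`, average linkage, cut
#' at `k`).
#'
#' @param X numeric matrix.
#' @param params reference [rf_params()].
#' @param n_runs number of repeat runs (>= 2).
#' @param k optional number of clusters for label-agreement assessment.
#' @param mds_dims embedding dimensions used for the label agreement.
#' @return data.frame with one row per run: `seed`, `mean_abs_diff`,
#'   `max_abs_diff`, and `ari` (NA when `k` is NULL).
#' @export
stability_assessment <- function(X, params = rf_params(), n_runs = 10,
                                 k = NULL, mds_dims = 3) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  ref <- rf_dissimilarity(X, params)
  ref_labels <- if (!is.null(k))
    cut_tree(average_linkage(classical_mds(ref, mds_dims)), k) else NULL
  res <- lapply(seq_len(n_runs), function(i) {
    p <- params
    p$seed <- params$seed + i
    run <- rf_dissimilarity(X, p)
    ari <- NA_real_
    if (!is.null(k)) {
      lab <- cut_tree(average_linkage(classical_mds(run, mds_dims)), k)
      ari <- mclust::adjustedRandIndex(lab, ref_labels)
    }
    data.frame(seed = p$seed,
               mean_abs_diff = mean(abs(run$d - ref$d)),
               max_abs_diff = max(abs(run$d - ref$d)),
               ari = ari)
  })
  do.call(rbind, res)
}

#' Classical multidimensional scaling
#'
#' Double-centers the squared dissimilarities (`B = -1/2 J D^2 J`),
#' eigendecomposes, and returns coordinates scaled by the square roots of
#' the top `d` positive eigenvalues. If fewer than `d` eigenvalues are
#' positive, the available dimensions are returned with a warning. Column
#' signs are canonicalized (first nonzero coordinate of each axis made
#' positive) so results are reproducible across platforms.
#'
#' @param D an `rf_dissimilarity`, `dist`, or square symmetric matrix.
#' @param d number of dimensions to retain (>= 1).
#' @return An `mds_embedding`: `points` (n x d), `eigenvalues` (all n,
#'   descending, for scree inspection), `d`.
#' @export
classical_mds <- function(D, d = 3) {
  if (inherits(D, "rf_dissimilarity")) D <- D$d
  D <- as.matrix(D)
  n <- nrow(D)
  if (d < 1) stop("d must be >= 1")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > max(1e-12, 1e-9 * abs(eig$values[1])))
  d_eff <- as.integer(min(d, length(pos)))
  if (d_eff < d)
    warning("only ", d_eff, " positive eigenvalue(s); returning ",
            d_eff, " dimension(s)")
  if (d_eff == 0) stop("no positive eigenvalues; degenerate dissimilarity")
  pts <- eig$vectors[, seq_len(d_eff), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(d_eff)]), d_eff)
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(D)
  structure(list(points = pts, eigenvalues = eig$values, d = d_eff),
            class = "mds_embedding")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering on the Euclidean distances between embedded
#' coordinates, merging at each step the pair of clusters with the
#' smallest mean pairwise inter-cluster distance. The full merge history
#' and cophenetic heights are retained.
#'
#' @param embedding an `mds_embedding` or numeric coordinate matrix.
#' @return A `cluster_solution`: `hclust` (merge history), `heights`,
#'   `cophenetic` (dist), `n`.
#' @export
average_linkage <- function(embedding) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points
         else as.matrix(embedding)
  if (nrow(pts) < 2) stop("need at least 2 points")
  hc <- stats::hclust(stats::dist(pts), method = "average")
  structure(list(hclust = hc, heights = hc$height,
                 cophenetic = stats::cophenetic(hc), n = nrow(pts)),
            class = "cluster_solution")
}

#' Cut the dendrogram into k subtypes
#'
#' Cuts the merge history at `k` groups and relabels clusters
#' deterministically by decreasing size (label 1 = largest; ties broken by
#' first occurrence).
#'
#' @param solution a `cluster_solution`.
#' @param k number of clusters (1..n).
#' @return Integer label vector named by subject id.
#' @export
cut_tree <- function(solution, k) {
  if (k < 1 || k > solution$n) stop("k out of range [1, ", solution$n, "]")
  raw <- stats::cutree(solution$hclust, k = k)
  sizes <- table(raw)
  first_seen <- vapply(names(sizes), function(g) min(which(raw == g)),
                       numeric(1))
  ord <- names(sizes)[order(-as.integer(sizes), first_seen)]
  stats::setNames(match(as.character(raw), ord), names(raw))
}
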