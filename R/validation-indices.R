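#' Cluster-validation indices
#'
#' Four classical internal validation indices computed on the clustering
#' coordinates (here, the MDS embedding): Calinski-Harabasz (higher
#' better), Davies-Bouldin (lower better), Dunn (higher better) and mean
#' Silhouette (higher better). Degenerate geometry (zero within-cluster
#' scatter, coincident centroids, zero diameters) yields an `Inf` sentinel
#' with attribute `"sentinel" = TRUE` rather than a silent drop.
#'
#' @param X numeric coordinate matrix (points x dims).
#' @param labels cluster labels, one per row of `X`; 2 <= k < n, no empty
#'   cluster.
#' @return A single numeric score.
#' @name validation_indices
NULL

check_partition <- function(X, labels) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) stop("labels must match rows of X")
  labels <- as.character(labels)
  k <- length(unique(labels))
  if (k < 2 || k > nrow(X))
    stop("need 2 <= k <= n, got k = ", k, ", n = ", nrow(X))
  list(X = X, labels = labels, k = k)
}

centroid_stats <- function(X, labels) {
  groups <- split(seq_len(nrow(X)), labels)
  cent <- t(vapply(groups, function(idx)
    colMeans(X[idx, , drop = FALSE]), numeric(ncol(X))))
  list(groups = groups, centroids = cent)
}

#' @rdname validation_indices
#' @export
calinski_harabasz <- function(X, labels) {
  p <- check_partition(X, labels)
  cs <- centroid_stats(p$X, p$labels)
  grand <- colMeans(p$X)
  n <- nrow(p$X)
  ssb <- sum(vapply(seq_along(cs$groups), function(i)
    length(cs$groups[[i]]) * sum((cs$centroids[i, ] - grand)^2), numeric(1)))
  ssw <- sum(vapply(seq_along(cs$groups), function(i) {
    idx <- cs$groups[[i]]
    sum(sweep(p$X[idx, , drop = FALSE], 2, cs$centroids[i, ])^2)
  }, numeric(1)))
  if (ssw == 0) return(structure(Inf, sentinel = TRUE))
  (ssb / (p$k - 1)) / (ssw / (n - p$k))
}

#' @rdname validation_indices
#' @export
davies_bouldin <- function(X, labels) {
  p <- check_partition(X, labels)
  cs <- centroid_stats(p$X, p$labels)
  k <- p$k
  s <- vapply(seq_len(k), function(i) {
    idx <- cs$groups[[i]]
    mean(sqrt(rowSums(sweep(p$X[idx, , drop = FALSE], 2,
                            cs$centroids[i, ])^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(cs$centroids))
  if (any(dc[upper.tri(dc)] == 0)) {
    warning("coincident centroids; Davies-Bouldin undefined")
    return(structure(Inf, sentinel = TRUE))
  }
  r <- vapply(seq_len(k), function(i)
    max(((s[i] + s)[-i]) / dc[i, -i]), numeric(1))
  mean(r)
}

#' @rdname validation_indices
#' @export
dunn_index <- function(X, labels) {
  p <- check_partition(X, labels)
  d <- as.matrix(stats::dist(p$X))
  same <- outer(p$labels, p$labels, "==")
  diag(same) <- NA
  within <- d[which(same)]
  between <- d[which(!same)]
  max_diam <- if (length(within)) max(within) else 0
  if (max_diam == 0) {
    warning("all clusters have zero diameter; Dunn undefined")
    return(structure(Inf, sentinel = TRUE))
  }
  min(between) / max_diam
}

#' @rdname validation_indices
#' @export
silhouette_index <- function(X, labels) {
  mean(silhouette_widths(X, labels))
}

#' Per-point silhouette widths
#'
#' `s = (b - a) / max(a, b)` with `a` the mean distance to the point's own
#' cluster (excluding itself) and `b` the smallest mean distance to
#' another cluster. Singleton points score 0 by convention, as do points
#' with `a = b = 0`.
#'
#' @inheritParams validation_indices
#' @return Numeric vector of widths in [-1, 1].
#' @export
silhouette_widths <- function(X, labels) {
  p <- check_partition(X, labels)
  d <- as.matrix(stats::dist(p$X))
  groups <- split(seq_len(nrow(p$X)), p$labels)
  vapply(seq_len(nrow(p$X)), function(i) {
    own <- setdiff(groups[[p$labels[i]]], i)
    if (!length(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(groups[names(groups) != p$labels[i]],
                    function(idx) mean(d[i, idx]), numeric(1)))
    if (a == 0 && b == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
}

#' k-selection report across candidate cluster counts
#'
#' Cuts the dendrogram at every k in `k_range`, evaluates the four
#' validation indices on the embedding coordinates, and recommends the k
#' winning the majority vote of the per-index optima (max for
#' Calinski-Harabasz, Dunn and Silhouette; min for Davies-Bouldin), with
#' ties broken toward smaller k. The choice of cluster count in practice
#' also weighs prior knowledge; `override_k`, when given, is recorded as
#' the recommendation with the vote retained in the table.
#'
#' @param embedding an `mds_embedding` (or coordinate matrix).
#' @param solution the `cluster_solution` to cut.
#' @param k_range integer vector of candidate k (within [2, n-1]).
#' @param override_k optional manual choice.
#' @return A `k_selection` list: `table` (data.frame k x indices),
#'   `votes`, `recommended_k`, `override`.
#' @export
k_selection_report <- function(embedding, solution, k_range = 2:8,
                               override_k = NULL) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points
         else as.matrix(embedding)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(pts) - 1)
    stop("k_range must lie within [2, n-1]")
  tab <- do.call(rbind, lapply(k_range, function(k) {
    lab <- cut_tree(solution, k)
    data.frame(k = k,
               calinski_harabasz = as.numeric(calinski_harabasz(pts, lab)),
               davies_bouldin = as.numeric(davies_bouldin(pts, lab)),
               dunn = as.numeric(dunn_index(pts, lab)),
               silhouette = as.numeric(silhouette_index(pts, lab)))
  }))
  votes <- c(
    calinski_harabasz = tab$k[which.max(tab$calinski_harabasz)],
    davies_bouldin = tab$k[which.min(tab$davies_bouldin)],
    dunn = tab$k[which.max(tab$dunn)],
    silhouette = tab$k[which.max(tab$silhouette)])
  vote_counts <- table(votes)
  winners <- as.integer(names(vote_counts)[vote_counts == max(vote_counts)])
  recommended <- min(winners)
  structure(list(table = tab, votes = votes,
                 recommended_k = if (is.null(override_k)) recommended
                                 else as.integer(override_k),
                 majority_k = recommended,
                 override = !is.null(override_k),
                 direction = c(calinski_harabasz = "higher",
                               davies_bouldin = "lower",
                               dunn = "higher", silhouette = "higher")),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("votes:", paste(names(x$votes), x$votes, sep = "=", collapse = ", "),
      "\nrecommended k:", x$recommended_k,
      if (x$override) "(manual override)" else "", "\n")
  invisible(x)
}
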