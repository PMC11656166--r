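# Independent brute-force oracles. These deliberately use naive loop-based
# formulations, separate from the package's vectorized implementations.

# O(n^3) UPGMA: repeatedly merge the cluster pair with smallest mean
# pairwise distance, tracking merge heights
oracle_upgma_heights <- function(X) {
  d <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# oracle cluster labels at k via the same greedy merging
oracle_upgma_cut <- function(X, k) {
  d <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  labels <- integer(nrow(X))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracle_calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- unique(labels)
  grand <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (g in ks) {
    idx <- which(labels == g)
    cen <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * sum((cen - grand)^2)
    for (i in idx) ssw <- ssw + sum((X[i, ] - cen)^2)
  }
  (ssb / (length(ks) - 1)) / (ssw / (n - length(ks)))
}

oracle_davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  ks <- unique(labels)
  cen <- lapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]))
  s <- vapply(seq_along(ks), function(i) {
    idx <- which(labels == ks[i])
    mean(vapply(idx, function(r) euclid(X[r, ], cen[[i]]), numeric(1)))
  }, numeric(1))
  total <- 0
  for (i in seq_along(ks)) {
    worst <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      r <- (s[i] + s[j]) / euclid(cen[[i]], cen[[j]])
      if (r > worst) worst <- r
    }
    total <- total + worst
  }
  total / length(ks)
}

oracle_dunn <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  min_between <- Inf
  max_within <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- euclid(X[i, ], X[j, ])
      if (labels[i] == labels[j]) {
        if (dij > max_within) max_within <- dij
      } else if (dij < min_between) min_between <- dij
    }
  }
  min_between / max_within
}

oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) {
      widths[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) euclid(X[i, ], X[j, ]), numeric(1)))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      idx <- which(labels == g)
      m <- mean(vapply(idx, function(j) euclid(X[i, ], X[j, ]), numeric(1)))
      if (m < b) b <- m
    }
    widths[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(widths)
}

oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    ((length(x) - 1) * stats::sd(x) * stats::sd(y))
}
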