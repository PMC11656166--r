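test_that("contrast sample preserves marginals and destroys dependence", {
  set.seed(31)
  n <- 500
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n, 0, 0.1), b = z + rnorm(n, 0, 0.1),
             c = rep(3, n))
  ct <- make_contrast_sample(X, seed = 31)
  # constant column is reproduced exactly
  expect_identical(unname(ct[, "c"]), rep(3, n))
  # marginal moments preserved within CLT bounds
  expect_equal(mean(ct[, "a"]), mean(X[, "a"]), tolerance = 0.15)
  expect_equal(sd(ct[, "a"]), sd(X[, "a"]), tolerance = 0.15)
  # strong correlation (~0.98) collapses toward zero
  expect_gt(cor(X[, "a"], X[, "b"]), 0.9)
  expect_lt(abs(cor(ct[, "a"], ct[, "b"])), 0.15)
})

test_that("dissimilarity invariants hold across seeds and duplicates are closest", {
  set.seed(32)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("s%02d", 1:20), NULL))
  X[20, ] <- X[1, ]  # duplicated subject
  for (seed in 1:3) {
    ds <- rf_dissimilarity(X, rf_params(n_trees = 300, seed = seed))
    expect_identical(ds$d, t(ds$d))
    expect_equal(unname(diag(ds$d)), rep(0, 20))
    expect_true(all(ds$d >= 0 & ds$d <= 1))
    off <- ds$d[upper.tri(ds$d)]
    expect_equal(ds$d["s01", "s20"], min(off))
  }
})

test_that("separated blobs give smaller within- than between-blob dissimilarity", {
  for (seed in 1:5) {
    blobs <- make_blobs(30, rbind(rep(0, 4), rep(6, 4)), seed = seed)
    ds <- rf_dissimilarity(blobs$X, rf_params(n_trees = 500, seed = seed))
    same <- outer(blobs$labels, blobs$labels, "==")
    diag(same) <- NA
    expect_lt(mean(ds$d[which(same)]), mean(ds$d[which(!same)]))
  }
})

test_that("identical parameters and seed reproduce the dissimilarity exactly", {
  set.seed(33)
  X <- matrix(rnorm(15 * 5), 15, 5)
  a <- rf_dissimilarity(X, rf_params(n_trees = 200, seed = 4))
  b <- rf_dissimilarity(X, rf_params(n_trees = 200, seed = 4))
  expect_identical(a$d, b$d)
})

test_that("OOB tuning returns the minimizing grid cell deterministically", {
  blobs <- make_blobs(25, rbind(rep(0, 6), rep(4, 6)), seed = 34)
  # singleton grid returns that cell
  p1 <- tune_rf(blobs$X, mtry_grid = 3, nodesize_grid = 7, n_trees = 100,
                seed = 1)
  expect_identical(c(p1$mtry, p1$nodesize), c(3, 7L))
  # duplicated cells do not change the result
  p2 <- tune_rf(blobs$X, mtry_grid = c(2, 4), nodesize_grid = c(1, 5),
                n_trees = 150, seed = 2)
  p3 <- tune_rf(blobs$X, mtry_grid = c(2, 4, 4), nodesize_grid = c(1, 5, 5),
                n_trees = 150, seed = 2)
  expect_identical(c(p2$mtry, p2$nodesize), c(p3$mtry, p3$nodesize))
  # the selected cell attains the minimal recorded OOB error
  grid <- attr(p2, "grid")
  expect_equal(grid$oob_error[grid$mtry == p2$mtry &
                                grid$nodesize == p2$nodesize],
               min(grid$oob_error))
})

test_that("stability assessment is zero at the same seed and bookkeeps runs", {
  set.seed(35)
  X <- matrix(rnorm(24 * 5), 24, 5,
              dimnames = list(sprintf("p%02d", 1:24), NULL))
  st <- stability_assessment(X, rf_params(n_trees = 150, seed = 1),
                             n_runs = 2, k = 2)
  expect_identical(nrow(st), 2L)
  expect_true(all(c("mean_abs_diff", "max_abs_diff", "ari") %in% names(st)))
  # a run re-using the reference seed reproduces the reference matrix
  ref <- rf_dissimilarity(X, rf_params(n_trees = 150, seed = 1))
  again <- rf_dissimilarity(X, rf_params(n_trees = 150, seed = 1))
  expect_identical(max(abs(ref$d - again$d)), 0)
})

test_that("more trees shrink the between-run dissimilarity differences", {
  set.seed(36)
  X <- matrix(rnorm(20 * 5), 20, 5)
  st_small <- stability_assessment(X, rf_params(n_trees = 100, seed = 2),
                                   n_runs = 3)
  st_large <- stability_assessment(X, rf_params(n_trees = 4000, seed = 2),
                                   n_runs = 3)
  expect_lt(mean(st_large$mean_abs_diff), mean(st_small$mean_abs_diff))
})

test_that("classical MDS embeds Euclidean distances exactly", {
  set.seed(37)
  P <- matrix(rnorm(4 * 3), 4, 3)
  D <- as.matrix(dist(P))
  emb <- classical_mds(D, 3)
  expect_lt(max(abs(as.matrix(dist(emb$points)) - D)), 1e-8)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))

  # equilateral triangle of side 1 reconstructs all unit distances
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  emb_tri <- classical_mds(as.matrix(dist(tri)), 2)
  expect_equal(unname(as.matrix(dist(emb_tri$points))[upper.tri(diag(3))]),
               rep(1, 3), tolerance = 1e-10)
})

test_that("classical MDS agrees with the cmdscale oracle up to sign", {
  set.seed(38)
  P <- matrix(rnorm(12 * 5), 12, 5)
  D <- as.matrix(dist(P))
  emb <- classical_mds(D, 3)
  oracle <- stats::cmdscale(D, k = 3)
  for (j in 1:3) {
    mine <- unname(emb$points[, j])
    ref <- unname(oracle[, j])
    expect_true(isTRUE(all.equal(mine, ref, tolerance = 1e-8)) ||
                isTRUE(all.equal(mine, -ref, tolerance = 1e-8)))
  }
})

test_that("permuting MDS input rows permutes output rows identically", {
  set.seed(39)
  P <- matrix(rnorm(9 * 3), 9, 3)
  D <- as.matrix(dist(P))
  perm <- sample(9)
  emb <- classical_mds(D, 2)
  emb_p <- classical_mds(D[perm, perm], 2)
  # compare reconstructed distances, which are rotation/sign free
  expect_equal(as.matrix(dist(emb_p$points)),
               unname(as.matrix(dist(emb$points))[perm, perm]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("MDS warns when fewer than d positive eigenvalues exist", {
  # 3 collinear points span 1 dimension
  P <- cbind(c(0, 1, 2))
  D <- as.matrix(dist(P))
  expect_warning(emb <- classical_mds(D, 3), "positive eigenvalue")
  expect_identical(emb$d, 1L)
  expect_equal(dim(emb$points), c(3L, 1L))
})

test_that("average linkage reproduces the brute-force UPGMA oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    sol <- average_linkage(X)
    expect_equal(sol$heights, oracle_upgma_heights(X), tolerance = 1e-10)
    for (k in 2:min(4, n - 1)) {
      ari <- mclust::adjustedRandIndex(cut_tree(sol, k),
                                       oracle_upgma_cut(X, k))
      expect_equal(ari, 1)
    }
  }
})

test_that("UPGMA base cases: pair merge height and zero-height duplicates", {
  two <- rbind(c(0, 0), c(3, 4))
  sol <- average_linkage(two)
  expect_equal(sol$heights, 5)
  dup <- rbind(c(1, 1), c(2, 5), c(1, 1))
  expect_equal(average_linkage(dup)$heights[1], 0)
})

test_that("cut_tree labels are size-ordered and bounded", {
  blobs <- make_blobs(c(5), rbind(rep(0, 2), rep(8, 2), rep(-8, 2)),
                      seed = 40)
  sol <- average_linkage(blobs$X)
  expect_identical(unname(cut_tree(sol, 1)), rep(1L, 15))
  expect_identical(sort(unname(cut_tree(sol, 15))), 1:15)
  expect_error(cut_tree(sol, 16), "out of range")
  expect_error(cut_tree(sol, 0), "out of range")
  # three well-separated blobs are recovered perfectly at k=3
  lab <- cut_tree(sol, 3)
  expect_equal(mclust::adjustedRandIndex(lab, blobs$labels), 1)
  # labels ordered by decreasing cluster size
  lab_sizes <- table(cut_tree(sol, 2))
  expect_true(lab_sizes[1] >= lab_sizes[2])
})
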