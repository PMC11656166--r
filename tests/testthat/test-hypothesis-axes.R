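# builds an n-subject analysis matrix with prescribed hippocampal and
# cortical composite values (amygdala mirrors hippocampus; both
# association regions equal)
composite_matrix <- function(hip, ctx, other = 10, modality = "MRI") {
  n <- length(hip)
  vals <- cbind(hippocampus = hip, amygdala = hip, ctx_assoc_a = ctx,
                ctx_assoc_b = ctx, ctx_primary = rep(other, n),
                pons = rep(other, n))
  rownames(vals) <- sprintf("A%03d", seq_len(n))
  as_state(vals, modality,
           if (modality == "MRI") "icv-adjusted" else "global-normalized")
}

test_that("hippocampus-to-cortex ratio is the composite mean quotient", {
  m <- composite_matrix(hip = c(4, 20), ctx = c(20, 20))
  r <- hippocampus_cortex_ratio(m, toy_atlas())
  expect_equal(unname(r), c(0.2, 1))
})

test_that("two-step classifier matches exhaustive enumeration on a monotone cohort", {
  # ratios strictly increasing with subject index, composites consistent:
  # low index = low hip & high ctx (limbic pattern), high index = reverse
  n <- 16
  hip <- seq(2, 5, length.out = n)
  ctx <- seq(30, 15, length.out = n)
  m <- composite_matrix(hip, ctx)
  res <- classify_hypothesis_driven(m, toy_atlas())
  ratio <- hip / ctx
  q <- quantile(ratio, c(0.25, 0.75), names = FALSE)
  expected <- ifelse(ratio < q[1] & hip < median(hip) & ctx > median(ctx),
                     "Limbic Predominant",
              ifelse(ratio > q[2] & hip > median(hip) & ctx < median(ctx),
                     "Cortical Predominant", "Typical"))
  expect_identical(res$label, expected)
  # bottom and top quartiles are the extremes, middle is Typical
  expect_identical(res$label[1:4], rep("Limbic Predominant", 4))
  expect_identical(res$label[13:16], rep("Cortical Predominant", 4))
  expect_identical(res$label[5:12], rep("Typical", 8))
  th <- attr(res, "thresholds")
  expect_equal(unname(th[c("ratio_q25", "ratio_q75")]), q)
})

test_that("identical subjects all classify as Typical", {
  m <- composite_matrix(rep(3, 10), rep(20, 10))
  expect_message(res <- classify_hypothesis_driven(m, toy_atlas()),
                 "threshold")
  expect_identical(unique(res$label), "Typical")
})

test_that("step 2 vetoes a low-ratio subject whose composites disagree", {
  # subject 1 has the lowest ratio but also the highest hippocampal
  # composite: provisional Limbic Predominant must revert to Typical
  hip <- c(9, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0, 4.2, 4.4, 4.6, 4.8, 5.0)
  ctx <- c(60, 19.0, 18.6, 18.2, 17.8, 17.4, 17.0, 16.6, 16.2, 15.8,
           15.4, 15.0)
  m <- composite_matrix(hip, ctx)
  res <- classify_hypothesis_driven(m, toy_atlas())
  expect_identical(res$provisional[1], "Limbic Predominant")
  expect_identical(res$label[1], "Typical")
})

test_that("classification is invariant to uniform monotone rescaling", {
  set.seed(51)
  hip <- runif(20, 2, 6)
  ctx <- runif(20, 14, 30)
  base <- classify_hypothesis_driven(composite_matrix(hip, ctx), toy_atlas())
  scaled <- classify_hypothesis_driven(
    composite_matrix(hip * 3.7, ctx * 3.7), toy_atlas())
  expect_identical(base$label, scaled$label)
  # labels always partition the sample
  expect_identical(nrow(base), 20L)
  expect_true(all(base$label %in% c("Limbic Predominant", "Typical",
                                    "Cortical Predominant")))
})

test_that("hypothesis classes enrich for the matching planted templates", {
  hits <- 0
  for (seed in 1:5) {
    fx <- prep_cohort(seed = seed + 60)
    mri_ad <- subset_subjects(fx$pre$mri_adjusted, fx$ad_ids)
    res <- classify_hypothesis_driven(mri_ad, fx$atlas)
    truth <- fx$cohort$truth$template_mri[match(fx$ad_ids,
                                                fx$cohort$truth$subject_id)]
    lp_rate_in <- mean(res$label[truth == "Limbic Predominant"] ==
                         "Limbic Predominant")
    lp_rate_out <- mean(res$label[truth != "Limbic Predominant"] ==
                          "Limbic Predominant")
    if (lp_rate_in > lp_rate_out) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("axis coordinates min-max normalize over the analysis sample", {
  set.seed(52)
  n <- 12
  hipv <- runif(n, 2, 6)
  ctxv <- runif(n, 14, 30)
  mri <- composite_matrix(hipv, ctxv)
  fdg <- composite_matrix(runif(n, 0.8, 1.2), runif(n, 0.9, 1.4),
                          modality = "FDG")
  coords <- compute_axes(fdg, mri, toy_atlas())
  for (col in grep("^normalized", names(coords), value = TRUE)) {
    expect_gte(min(coords[[col]]), 0)
    expect_lte(max(coords[[col]]), 1)
    expect_identical(sum(coords[[col]] == 0), 1L)
    expect_identical(sum(coords[[col]] == 1), 1L)
  }
  # severity definitions: MRI total volume, FDG mean cortical uptake
  expect_equal(coords$severity_mri,
               unname(rowSums(mri$values[, 1:5])))
  expect_equal(coords$severity_fdg,
               unname(rowMeans(fdg$values[, c("ctx_assoc_a", "ctx_assoc_b",
                                              "ctx_primary")])))
  # two subjects force normalized values {0,1}
  two <- compute_axes(subset_subjects(fdg, sprintf("A%03d", 1:2)),
                      subset_subjects(mri, sprintf("A%03d", 1:2)),
                      toy_atlas())
  expect_setequal(two$normalized_severity_mri, c(0, 1))
  expect_error(compute_axes(subset_subjects(fdg, "A001"),
                            subset_subjects(mri, "A001"), toy_atlas()),
               "at least 2")
})

test_that("subtype axis summaries are convex means of coordinates", {
  set.seed(53)
  mri <- composite_matrix(runif(10, 2, 6), runif(10, 14, 30))
  fdg <- composite_matrix(runif(10, 0.8, 1.2), runif(10, 0.9, 1.4),
                          modality = "FDG")
  coords <- compute_axes(fdg, mri, toy_atlas())
  labs <- stats::setNames(c("solo", rep("rest", 9)), coords$subject_id)
  summ <- subtype_axis_summary(coords, labs)
  solo <- summ[summ$subtype == "solo", ]
  expect_equal(solo$mean_value[solo$modality == "FDG" &
                                 solo$measure == "typicality"],
               coords$normalized_typicality_fdg[1])
  expect_true(all(summ$mean_value >= 0 & summ$mean_value <= 1))
  # single shared label reduces to the sample means
  all_one <- subtype_axis_summary(coords, stats::setNames(
    rep("All", 10), coords$subject_id))
  expect_equal(all_one$mean_value[all_one$modality == "MRI" &
                                    all_one$measure == "severity"],
               mean(coords$normalized_severity_mri))
})

test_that("axis correlations match the closed-form Pearson oracle", {
  coords <- data.frame(
    subject_id = sprintf("A%03d", 1:5),
    typicality_fdg = c(0.1, 0.3, 0.2, 0.5, 0.4),
    severity_fdg = c(1.2, 1.0, 1.4, 0.9, 1.1),
    typicality_mri = c(0.15, 0.32, 0.18, 0.45, 0.41),
    severity_mri = c(5200, 5100, 5400, 4900, 5000))
  tab <- axis_correlations(coords)
  r_oracle <- oracle_pearson(coords$typicality_fdg, coords$severity_fdg)
  row1 <- tab[tab$pair == "typicality_fdg ~ severity_fdg", ]
  expect_equal(row1$r, r_oracle, tolerance = 1e-12)
  expect_equal(row1$r_squared, r_oracle^2, tolerance = 1e-12)
  expect_equal(row1$p_value,
               cor.test(coords$typicality_fdg, coords$severity_fdg)$p.value)
  # identical vectors give r = 1
  coords$severity_mri <- coords$typicality_mri
  tab2 <- axis_correlations(coords)
  expect_equal(tab2$r[tab2$pair == "typicality_fdg ~ typicality_mri"],
               cor(coords$typicality_fdg, coords$typicality_mri))
})

test_that("independent axes show near-zero R-squared at n=500", {
  set.seed(54)
  coords <- data.frame(
    subject_id = sprintf("A%03d", 1:500),
    typicality_fdg = rnorm(500), severity_fdg = rnorm(500),
    typicality_mri = rnorm(500), severity_mri = rnorm(500))
  tab <- axis_correlations(coords)
  expect_lt(max(tab$r_squared), 0.03)
})

test_that("method agreement percentages follow the hand-counted definition", {
  ids <- sprintf("A%03d", 1:10)
  dd <- stats::setNames(c(rep("cluster1", 8), rep("cluster2", 2)), ids)
  hyp <- stats::setNames(c(rep("Limbic Predominant", 6),
                           rep("Typical", 4)), ids)
  map <- c(cluster1 = "Limbic Predominant", cluster2 = "Cortical Predominant")
  tab <- method_agreement(dd, hyp, map)
  lp <- tab[tab$class == "Limbic Predominant", ]
  expect_identical(lp$n_data_driven, 8L)
  expect_identical(lp$n_both, 6L)
  expect_equal(lp$agreement_pct, 75)
  # identical labelings agree 100%; disjoint ones 0%
  same <- stats::setNames(rep("Limbic Predominant", 10), ids)
  tab2 <- method_agreement(same, same,
                           c("Limbic Predominant" = "Limbic Predominant"))
  expect_equal(tab2$agreement_pct[tab2$class == "Limbic Predominant"], 100)
  tab3 <- method_agreement(
    stats::setNames(rep("cluster1", 10), ids),
    stats::setNames(rep("Typical", 10), ids), map)
  expect_equal(tab3$agreement_pct[tab3$class == "Limbic Predominant"], 0)
})
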