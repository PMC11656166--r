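#' Cross-modality subtype crossover table
#'
#' Contingency table of the paired subtype allocations (FDG rows, MRI
#' columns) with row-normalized percentages — each row divides by the
#' total number of cases of that FDG subtype — and the alluvial-plot edge
#' list.
#'
#' @param fdg_labels,mri_labels label vectors named by subject id.
#' @return A `crossover_table`: `counts` (matrix), `percentages` (rows sum
#'   to 100), `edges` (data.frame `fdg_label`, `mri_label`, `count`), `n`.
#' @export
crossover <- function(fdg_labels, mri_labels) {
  ids <- intersect(names(fdg_labels), names(mri_labels))
  if (!length(ids)) stop("no common subjects between modalities")
  counts <- table(fdg = as.character(fdg_labels[ids]),
                  mri = as.character(mri_labels[ids]))
  counts <- unclass(counts)
  pct <- 100 * counts / rowSums(counts)
  edges <- as.data.frame(as.table(counts), stringsAsFactors = FALSE)
  names(edges) <- c("fdg_label", "mri_label", "count")
  edges <- edges[edges$count > 0, ]
  rownames(edges) <- NULL
  structure(list(counts = counts, percentages = pct, edges = edges,
                 n = length(ids)),
            class = "crossover_table")
}

#' Overall cross-modality agreement
#'
#' Maps each modality's subtype labels onto shared classes (e.g.
#' cortical / limbic / other) and reports the percentage of paired
#' subjects whose mapped classes coincide.
#'
#' @param fdg_labels,mri_labels label vectors named by subject id.
#' @param equivalence_map named character vector mapping every subtype
#'   label to its shared class; an unmapped label is an error naming it.
#' @return Percentage in [0, 100].
#' @export
overall_agreement <- function(fdg_labels, mri_labels, equivalence_map) {
  ids <- intersect(names(fdg_labels), names(mri_labels))
  if (!length(ids)) stop("no common subjects between modalities")
  map_class <- function(lab, side) {
    unmapped <- setdiff(unique(lab), names(equivalence_map))
    if (length(unmapped))
      stop("unmapped ", side, " label(s): ", paste(unmapped, collapse = ", "))
    unname(equivalence_map[lab])
  }
  f <- map_class(as.character(fdg_labels[ids]), "FDG")
  m <- map_class(as.character(mri_labels[ids]), "MRI")
  100 * mean(f == m)
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Orders the raw p-values ascending and sets
#' `adjusted_i = max_{j <= i} (1 - (1 - p_j)^(m - j + 1))`, capped at 1,
#' returning the values in the original order. Adjusted values are never
#' below the raw values and are monotone in raw-p rank.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Vector of adjusted p-values.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out[is.na(p)] <- NA
  out
}

#' Compare variables across subtypes
#'
#' Omnibus comparison of demographic/clinical variables across subtype
#' groups: chi-squared tests for categorical variables, Kruskal-Wallis
#' for continuous, with family-wise Holm-Sidak adjustment over all
#' variables tested. Where the omnibus adjusted p is below `alpha`,
#' post hoc pairwise tests (pairwise chi-squared / Wilcoxon rank-sum)
#' are run with their own Holm-Sidak family per variable.
#'
#' @param data data.frame of variables (rows = subjects).
#' @param labels group labels aligned to `data` rows (or named by
#'   `data$subject_id` when present).
#' @param types named character vector, `"categorical"` or `"continuous"`
#'   per tested variable.
#' @param alpha significance level for triggering post hoc tests.
#' @return A `group_comparison`: `table` (variable, type, test,
#'   statistic, p_raw, p_adjusted, low_expected_counts flag), `posthoc`
#'   (list of data.frames per significant variable), `alpha`.
#' @export
group_compare <- function(data, labels, types, alpha = 0.05) {
  if (!is.null(data$subject_id) && !is.null(names(labels)))
    labels <- labels[match(data$subject_id, names(labels))]
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 groups")
  vars <- names(types)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("variable(s) not in data: ", paste(missing_vars, collapse = ", "))

  run_test <- function(v) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(labels)
    if (types[[v]] == "categorical") {
      tab <- table(labels[ok], x[ok])
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      low <- any(expected < 1)
      if (low) warning("expected cell count < 1 for variable ", v)
      ht <- suppressWarnings(stats::chisq.test(tab))
      c(stat = unname(ht$statistic), p = ht$p.value, low = low,
        test = "chi-squared")
    } else {
      ht <- stats::kruskal.test(x[ok], factor(labels[ok]))
      c(stat = unname(ht$statistic), p = ht$p.value, low = FALSE,
        test = "kruskal-wallis")
    }
  }
  res <- lapply(vars, run_test)
  tab <- data.frame(
    variable = vars,
    type = unname(types[vars]),
    test = vapply(res, function(r) r[["test"]], character(1)),
    statistic = vapply(res, function(r) as.numeric(r[["stat"]]), numeric(1)),
    p_raw = vapply(res, function(r) as.numeric(r[["p"]]), numeric(1)),
    low_expected_counts = vapply(res, function(r) as.logical(r[["low"]]),
                                 logical(1)),
    stringsAsFactors = FALSE)
  tab$p_adjusted <- holm_sidak(tab$p_raw)

  posthoc <- list()
  groups <- sort(unique(labels))
  for (v in tab$variable[!is.na(tab$p_adjusted) & tab$p_adjusted < alpha]) {
    prs <- utils::combn(groups, 2, simplify = FALSE)
    ph <- do.call(rbind, lapply(prs, function(pr) {
      sel <- labels %in% pr & !is.na(data[[v]])
      if (types[[v]] == "categorical") {
        ht <- suppressWarnings(stats::chisq.test(
          table(labels[sel], data[[v]][sel])))
      } else {
        ht <- suppressWarnings(stats::wilcox.test(
          data[[v]][sel & labels == pr[1]], data[[v]][sel & labels == pr[2]]))
      }
      data.frame(group1 = pr[1], group2 = pr[2],
                 p_raw = ht$p.value, stringsAsFactors = FALSE)
    }))
    ph$p_adjusted <- holm_sidak(ph$p_raw)
    posthoc[[v]] <- ph
  }
  structure(list(table = tab, posthoc = posthoc, alpha = alpha),
            class = "group_comparison")
}

#' Per-subtype demographic and clinical summary
#'
#' Mean (sample SD, n-1 denominator) for continuous variables and count
#' (percent) for categoricals, per subtype, with an optional reference
#' group row appended — the layout of a clinical characteristics table.
#'
#' @param data data.frame of subject-level variables.
#' @param labels subtype labels aligned to `data` rows (or named by
#'   `data$subject_id`).
#' @param types named character vector per summarized variable.
#' @param reference_data optional data.frame summarized as one appended
#'   reference row (e.g. the control group).
#' @param reference_label row label for the reference group.
#' @return Long-format data.frame: `group`, `n`, `pct_of_sample`,
#'   `variable`, `summary`, `mean`/`sd` or `count`/`pct`.
#' @export
demographics_table <- function(data, labels, types,
                               reference_data = NULL,
                               reference_label = "Cognitively Normal") {
  if (!is.null(data$subject_id) && !is.null(names(labels)))
    labels <- labels[match(data$subject_id, names(labels))]
  labels <- as.character(labels)
  n_total <- length(labels)
  summarize_group <- function(df, group, n_group, pct) {
    do.call(rbind, lapply(names(types), function(v) {
      x <- df[[v]]
      x <- x[!is.na(x)]
      if (types[[v]] == "continuous") {
        data.frame(group = group, n = n_group, pct_of_sample = pct,
                   variable = v,
                   summary = sprintf("%.3g (%.3g)", mean(x), stats::sd(x)),
                   mean = mean(x), sd = stats::sd(x),
                   count = NA_real_, count_pct = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        cnt <- sum(x %in% c(TRUE, "positive", "F", 1))
        data.frame(group = group, n = n_group, pct_of_sample = pct,
                   variable = v,
                   summary = sprintf("%d (%.1f%%)", cnt,
                                     100 * cnt / length(x)),
                   mean = NA_real_, sd = NA_real_,
                   count = cnt, count_pct = 100 * cnt / length(x),
                   stringsAsFactors = FALSE)
      }
    }))
  }
  out <- do.call(rbind, lapply(sort(unique(labels)), function(g) {
    idx <- labels == g
    summarize_group(data[idx, , drop = FALSE], g, sum(idx),
                    100 * sum(idx) / n_total)
  }))
  if (!is.null(reference_data))
    out <- rbind(out, summarize_group(reference_data, reference_label,
                                      nrow(reference_data), NA_real_))
  rownames(out) <- NULL
  out
}
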