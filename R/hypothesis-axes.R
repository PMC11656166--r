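#' Hippocampus-to-cortex ratio
#'
#' Mean value over hippocampal regions divided by the mean over
#' cortical-association regions, per subject. Low ratios indicate
#' limbic-predominant neurodegeneration (for both volumes and uptake the
#' same low-ratio convention applies, since lower values mean worse in
#' either modality).
#'
#' @param values `roi_matrix` in an analysis state (`"icv-adjusted"`
#'   volume or `"global-normalized"` uptake).
#' @param atlas the `roi_atlas`.
#' @return Named numeric vector of ratios per subject.
#' @export
hippocampus_cortex_ratio <- function(values, atlas) {
  require_state(values, c("icv-adjusted", "global-normalized"))
  hip <- intersect(region_ids(values), atlas_regions(atlas, "hippocampus"))
  ctx <- intersect(region_ids(values),
                   atlas_regions(atlas, "cortical-association"))
  if (!length(hip)) stop("atlas defines no hippocampus region in matrix")
  if (!length(ctx)) stop("atlas defines no cortical-association region in matrix")
  rowMeans(values$values[, hip, drop = FALSE]) /
    rowMeans(values$values[, ctx, drop = FALSE])
}

#' Hypothesis-driven corticolimbic classification
#'
#' Two-step hippocampus-to-cortex ratio subtyping into Limbic Predominant
#' (low ratio), Cortical Predominant (high ratio) or Typical. Step 1
#' assigns provisional extremes by the 25th and 75th percentile of the
#' ratio in the analysis sample. Step 2 confirms a provisional label only
#' when the corticolimbic discordance is real relative to the sample
#' medians: Limbic Predominant requires hippocampal composite below the
#' median AND cortical composite above it; Cortical Predominant requires
#' the reverse; unconfirmed cases revert to Typical. Observations exactly
#' at a percentile threshold fall to the Typical side (logged).
#'
#' @param values `roi_matrix` restricted to the analysis (patient) sample,
#'   in an analysis state.
#' @param atlas the `roi_atlas`.
#' @return data.frame with `subject_id`, `label`, `ratio`,
#'   `hippocampal_composite`, `cortical_composite`, `provisional`; the
#'   thresholds used are attached as attribute `"thresholds"`.
#' @export
classify_hypothesis_driven <- function(values, atlas) {
  if (nrow(values$values) < 8)
    stop("need at least 8 subjects for percentile-based classification")
  ratio <- hippocampus_cortex_ratio(values, atlas)
  hip <- intersect(region_ids(values), atlas_regions(atlas, "hippocampus"))
  ctx <- intersect(region_ids(values),
                   atlas_regions(atlas, "cortical-association"))
  hip_comp <- rowMeans(values$values[, hip, drop = FALSE])
  ctx_comp <- rowMeans(values$values[, ctx, drop = FALSE])
  q <- stats::quantile(ratio, c(0.25, 0.75), names = FALSE)
  med_hip <- stats::median(hip_comp)
  med_ctx <- stats::median(ctx_comp)
  provisional <- ifelse(ratio < q[1], "Limbic Predominant",
                        ifelse(ratio > q[2], "Cortical Predominant",
                               "Typical"))
  n_ties <- sum(ratio == q[1] | ratio == q[2])
  if (n_ties)
    message(n_ties, " subject(s) exactly at a ratio threshold kept Typical")
  confirmed <- provisional
  lp <- provisional == "Limbic Predominant"
  confirmed[lp & !(hip_comp < med_hip & ctx_comp > med_ctx)] <- "Typical"
  cp <- provisional == "Cortical Predominant"
  confirmed[cp & !(hip_comp > med_hip & ctx_comp < med_ctx)] <- "Typical"
  out <- data.frame(subject_id = subject_ids(values), label = confirmed,
                    ratio = as.numeric(ratio),
                    hippocampal_composite = as.numeric(hip_comp),
                    cortical_composite = as.numeric(ctx_comp),
                    provisional = provisional,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(ratio_q25 = q[1], ratio_q75 = q[2],
                               median_hippocampal = med_hip,
                               median_cortical = med_ctx)
  out
}

#' Typicality and severity coordinates
#'
#' Places every analysis subject on the two axes of the corticolimbic
#' framework, per modality. Typicality is the hippocampus-to-cortex ratio
#' (volume-based for MRI, uptake-based for FDG). Severity is the total
#' grey-matter volume (sum over non-reference atlas regions) for MRI and
#' the total average cortical uptake (mean over cortical regions) for
#' FDG. Each measure is min-max normalized to [0, 1] over the analysis
#' sample.
#'
#' @param values_fdg `"global-normalized"` FDG `roi_matrix` (analysis
#'   sample).
#' @param values_mri `"icv-adjusted"` MRI `roi_matrix` (analysis sample).
#' @param atlas the `roi_atlas`.
#' @param ids optional subject ids to restrict to (default: subjects
#'   present in both matrices).
#' @return An `axis_coordinates` data.frame: per subject, raw and
#'   normalized typicality and severity for both modalities.
#' @export
compute_axes <- function(values_fdg, values_mri, atlas, ids = NULL) {
  require_state(values_fdg, "global-normalized")
  require_state(values_mri, "icv-adjusted")
  if (is.null(ids))
    ids <- intersect(subject_ids(values_fdg), subject_ids(values_mri))
  if (length(ids) < 2)
    stop("min-max normalization needs at least 2 subjects")
  f <- values_fdg$values[ids, , drop = FALSE]
  m <- values_mri$values[ids, , drop = FALSE]
  fdg_sub <- set_state(values_fdg, f, state = values_fdg$state)
  mri_sub <- set_state(values_mri, m, state = values_mri$state)
  ctx_all <- intersect(colnames(f), atlas_regions(atlas, "cortical"))
  nonref <- intersect(colnames(m), atlas_regions(atlas, "non-reference"))
  typ_fdg <- hippocampus_cortex_ratio(fdg_sub, atlas)
  typ_mri <- hippocampus_cortex_ratio(mri_sub, atlas)
  sev_fdg <- rowMeans(f[, ctx_all, drop = FALSE])
  sev_mri <- rowSums(m[, nonref, drop = FALSE])
  minmax <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) stop("zero range; min-max normalization undefined")
    (x - rng[1]) / diff(rng)
  }
  out <- data.frame(
    subject_id = ids,
    typicality_fdg = as.numeric(typ_fdg),
    severity_fdg = as.numeric(sev_fdg),
    typicality_mri = as.numeric(typ_mri),
    severity_mri = as.numeric(sev_mri),
    normalized_typicality_fdg = as.numeric(minmax(typ_fdg)),
    normalized_severity_fdg = as.numeric(minmax(sev_fdg)),
    normalized_typicality_mri = as.numeric(minmax(typ_mri)),
    normalized_severity_mri = as.numeric(minmax(sev_mri)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("axis_coordinates", "data.frame")
  out
}

#' Per-subtype mean axis coordinates
#'
#' Averages the normalized typicality and severity of each subtype, the
#' table behind the two-axis conceptual plot of subtypes.
#'
#' @param coords an `axis_coordinates` table.
#' @param labels subtype labels named by subject id (or aligned).
#' @return Long-format data.frame: `subtype`, `modality`, `measure`,
#'   `mean_value`, `n`.
#' @export
subtype_axis_summary <- function(coords, labels) {
  labels <- align_labels(labels, coords$subject_id)
  keep <- !is.na(labels)
  if (!all(keep)) warning("dropping ", sum(!keep), " unlabeled subject(s)")
  cols <- c(normalized_typicality_fdg = "typicality",
            normalized_severity_fdg = "severity",
            normalized_typicality_mri = "typicality",
            normalized_severity_mri = "severity")
  mods <- c("FDG", "FDG", "MRI", "MRI")
  do.call(rbind, lapply(split(which(keep), labels[keep]), function(idx) {
    data.frame(subtype = labels[idx[1]],
               modality = mods, measure = unname(cols),
               mean_value = vapply(names(cols), function(cl)
                 mean(coords[[cl]][idx]), numeric(1)),
               n = length(idx), row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Correlations between typicality and severity measures
#'
#' Pearson correlations (r, R^2, two-sided p) for the four pairings:
#' within-modality typicality vs severity (FDG, MRI), and cross-modality
#' severity vs severity and typicality vs typicality.
#'
#' @param coords an `axis_coordinates` table (>= 3 subjects).
#' @return data.frame with `pair`, `r`, `r_squared`, `p_value`, `n`.
#' @export
axis_correlations <- function(coords) {
  if (nrow(coords) < 3) stop("need at least 3 paired subjects")
  pairs <- list(
    c("typicality_fdg", "severity_fdg"),
    c("typicality_mri", "severity_mri"),
    c("severity_fdg", "severity_mri"),
    c("typicality_fdg", "typicality_mri"))
  do.call(rbind, lapply(pairs, function(p) {
    x <- coords[[p[1]]]; y <- coords[[p[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance in ", p[1], " or ", p[2],
              "; correlation undefined")
      return(data.frame(pair = paste(p, collapse = " ~ "), r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n = length(x), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(pair = paste(p, collapse = " ~ "),
               r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
               p_value = ct$p.value, n = length(x), stringsAsFactors = FALSE)
  }))
}

#' Agreement between data-driven and hypothesis-driven subtypes
#'
#' For each shared class (e.g. limbic-predominant, cortical-predominant),
#' the percentage of subjects assigned to the class by the data-driven
#' method that also carry it under the hypothesis-driven method:
#' `|both| / |data-driven| * 100`.
#'
#' @param data_driven_labels,hypothesis_labels label vectors named by
#'   subject id.
#' @param equivalence_map named character vector mapping data-driven
#'   subtype names to the hypothesis-driven class names (unmapped labels
#'   count as no class).
#' @return data.frame with `class`, `n_data_driven`, `n_both`,
#'   `agreement_pct` (NA when the class is absent under the data-driven
#'   method).
#' @export
method_agreement <- function(data_driven_labels, hypothesis_labels,
                             equivalence_map) {
  ids <- intersect(names(data_driven_labels), names(hypothesis_labels))
  if (!length(ids)) stop("no common subjects between label sets")
  dd <- unname(equivalence_map[data_driven_labels[ids]])
  hyp <- as.character(hypothesis_labels[ids])
  classes <- sort(unique(stats::na.omit(c(unname(equivalence_map), hyp))))
  do.call(rbind, lapply(classes, function(cl) {
    n_dd <- sum(dd == cl, na.rm = TRUE)
    n_both <- sum(dd == cl & hyp == cl, na.rm = TRUE)
    data.frame(class = cl, n_data_driven = n_dd, n_both = n_both,
               agreement_pct = if (n_dd > 0) 100 * n_both / n_dd
                               else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
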