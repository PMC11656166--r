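#' Fit the head-size adjustment model on controls
#'
#' Regresses each region's raw volume on estimated total intracranial
#' volume (ICV) in the cognitively normal group and stores the per-region
#' ordinary-least-squares slope together with the control-group mean ICV.
#' The fitted model is later applied unchanged to every group, so patient
#' volumes are residualized against the normative head-size relationship.
#'
#' @param volumes_cn raw MRI `roi_matrix` restricted to controls.
#' @param meta_cn matching `subject_meta` rows.
#' @return An `icv_model`: list with `beta` (named slope per region),
#'   `icv_mean`, and `n`.
#' @export
fit_icv_model <- function(volumes_cn, meta_cn) {
  require_state(volumes_cn, "raw")
  icv <- meta_cn$icv[match(subject_ids(volumes_cn), meta_cn$subject_id)]
  if (anyNA(icv)) stop("missing ICV for fitting subjects")
  if (length(icv) < 3) stop("need at least 3 control subjects to fit ICV model")
  if (stats::var(icv) == 0) stop("zero ICV variance in fitting sample")
  x <- icv - mean(icv)
  beta <- drop(crossprod(x, sweep(volumes_cn$values, 2,
                                  colMeans(volumes_cn$values)))) / sum(x^2)
  structure(list(beta = stats::setNames(beta, region_ids(volumes_cn)),
                 icv_mean = mean(icv), n = length(icv)),
            class = "icv_model")
}

#' Apply the head-size adjustment
#'
#' Element-wise residual adjustment
#' `adjusted = raw - beta * (ICV - ICV_mean)` using the slopes and mean ICV
#' fitted on controls, applied identically to every group.
#'
#' @param volumes raw MRI `roi_matrix`.
#' @param meta matching `subject_meta` rows.
#' @param model an `icv_model` from [fit_icv_model()].
#' @return An `"icv-adjusted"` `roi_matrix`.
#' @export
apply_icv_adjustment <- function(volumes, meta, model) {
  require_state(volumes, "raw")
  missing_regions <- setdiff(region_ids(volumes), names(model$beta))
  if (length(missing_regions))
    stop("region(s) missing from ICV model: ",
         paste(missing_regions, collapse = ", "))
  icv <- meta$icv[match(subject_ids(volumes), meta$subject_id)]
  if (anyNA(icv)) stop("missing ICV for adjusted subjects")
  adj <- volumes$values -
    outer(icv - model$icv_mean, model$beta[region_ids(volumes)])
  set_state(volumes, adj, state = "icv-adjusted")
}

#' Global-mean intensity normalization of uptake
#'
#' Divides each subject's regional uptake values by that subject's mean
#' uptake over all non-reference atlas regions, so every output row has
#' mean 1 over those regions. Reference regions are excluded from the mean
#' (keeping global-mean and reference-region scaling independent) and
#' dropped from the output, which covers grey-matter regions only.
#'
#' @param uptake raw FDG `roi_matrix`.
#' @param atlas the `roi_atlas` (identifies reference regions).
#' @return A `"global-normalized"`, dimensionless `roi_matrix`.
#' @export
normalize_global_mean <- function(uptake, atlas) {
  require_state(uptake, "raw")
  if (any(uptake$values <= 0)) stop("uptake values must be strictly positive")
  keep <- intersect(region_ids(uptake), atlas_regions(atlas, "non-reference"))
  if (!length(keep)) stop("no non-reference regions present")
  gm <- rowMeans(uptake$values[, keep, drop = FALSE])
  # reference regions are scaling machinery, not analysis features: the
  # output covers the grey-matter regions only
  set_state(uptake, uptake$values[, keep, drop = FALSE] / gm,
            units = "dimensionless", state = "global-normalized")
}

#' Reference-region scaling of uptake
#'
#' Divides each subject's regional uptake by the mean of that subject's
#' reference-region (pons-like) values, producing the SUVRs used as input
#' to the w-score neurodegeneration maps. Reference regions are dropped
#' from the output.
#'
#' @param uptake raw FDG `roi_matrix`.
#' @param atlas the `roi_atlas`.
#' @return A `"reference-scaled"` `roi_matrix` in SUVR units.
#' @export
scale_by_reference <- function(uptake, atlas) {
  require_state(uptake, "raw")
  ref <- intersect(region_ids(uptake), atlas_regions(atlas, "reference"))
  if (!length(ref)) stop("atlas defines no reference region present in matrix")
  refval <- rowMeans(uptake$values[, ref, drop = FALSE])
  if (any(refval <= 0)) stop("non-positive reference-region value")
  keep <- setdiff(region_ids(uptake), ref)
  set_state(uptake, uptake$values[, keep, drop = FALSE] / refval,
            units = "SUVR", state = "reference-scaled")
}

#' Screen for head-size outliers
#'
#' Regresses total (non-reference) regional volume on ICV and flags
#' subjects whose residual exceeds `n_sd` residual standard deviations, an
#' automated stand-in for plotting regional volumes against ICV to find
#' grossly mis-estimated segmentations. Flags are advisory; exclusion is
#' the caller's decision.
#'
#' @param volumes raw MRI `roi_matrix`.
#' @param meta matching `subject_meta` rows.
#' @param atlas the `roi_atlas`.
#' @param n_sd flagging threshold in residual SDs (default 4).
#' @return data.frame with `subject_id`, `total_volume`, `residual`,
#'   `flagged`.
#' @export
qc_screen <- function(volumes, meta, atlas, n_sd = 4) {
  keep <- intersect(region_ids(volumes), atlas_regions(atlas, "non-reference"))
  total <- rowSums(volumes$values[, keep, drop = FALSE])
  icv <- meta$icv[match(subject_ids(volumes), meta$subject_id)]
  if (length(total) < 10 || stats::var(icv) == 0) {
    warning("too few subjects (or degenerate ICV) for QC screen; no flags")
    return(data.frame(subject_id = subject_ids(volumes), total_volume = total,
                      residual = NA_real_, flagged = FALSE))
  }
  fit <- stats::lm(total ~ icv)
  res <- stats::residuals(fit)
  sd_res <- stats::sd(res)
  flagged <- if (is.finite(n_sd)) abs(res) > n_sd * sd_res
             else rep(FALSE, length(res))
  if (any(flagged))
    message("QC screen flagged ", sum(flagged), " subject(s): ",
            paste(subject_ids(volumes)[flagged], collapse = ", "))
  data.frame(subject_id = subject_ids(volumes), total_volume = total,
             residual = as.numeric(res), flagged = flagged)
}
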