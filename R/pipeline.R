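#' Run the data-driven subtyping pipeline for one modality
#'
#' Chains the clustering stages on an analysis-state regional matrix:
#' optional out-of-bag hyperparameter tuning, unsupervised random-forest
#' dissimilarity, classical MDS to `mds_dims` dimensions, average-linkage
#' hierarchical clustering, the four-index k-selection report, and the cut
#' at the recommended (or overridden) k.
#'
#' @param values `roi_matrix` in an analysis state (`"global-normalized"`
#'   uptake or `"icv-adjusted"` volume), typically restricted to the
#'   patient analysis sample.
#' @param n_trees trees per forest.
#' @param mds_dims embedding dimensions (default 3).
#' @param k_range candidate cluster counts.
#' @param tune run the OOB grid search first; otherwise `mtry` defaults to
#'   `floor(sqrt(p))` and `nodesize` to 1.
#' @param mtry_grid,nodesize_grid grids for [tune_rf()].
#' @param override_k manual cluster count (recorded; the index table is
#'   still produced).
#' @param seed integer seed for every stochastic stage.
#' @return A `subtype_pipeline` list: `params`, `dissimilarity`,
#'   `embedding`, `solution`, `k_report`, `k`, `labels` (size-ordered,
#'   named by subject).
#' @export
run_subtype_pipeline <- function(values, n_trees = 2000, mds_dims = 3,
                                 k_range = 2:8, tune = FALSE,
                                 mtry_grid = c(5, 9, 15, 27),
                                 nodesize_grid = c(1, 5, 10),
                                 override_k = NULL, seed = 1L) {
  require_state(values, c("global-normalized", "icv-adjusted"))
  X <- values$values
  params <- if (tune)
    tune_rf(X, mtry_grid, nodesize_grid, n_trees = n_trees, seed = seed)
  else rf_params(n_trees = n_trees, seed = seed)
  diss <- rf_dissimilarity(X, params)
  emb <- classical_mds(diss, mds_dims)
  sol <- average_linkage(emb)
  rep <- k_selection_report(emb, sol, k_range, override_k = override_k)
  k <- rep$recommended_k
  structure(list(params = params, dissimilarity = diss, embedding = emb,
                 solution = sol, k_report = rep, k = k,
                 labels = cut_tree(sol, k)),
            class = "subtype_pipeline")
}

#' Preprocess a two-modality cohort for analysis
#'
#' Runs the standard value transformations in one call: fits the ICV model
#' on the control subjects and adjusts all volumes; global-mean normalizes
#' the uptake matrix (clustering input) and reference-scales it (w-score
#' map input).
#'
#' @param meta `subject_meta` for the full cohort.
#' @param fdg,mri raw `roi_matrix` objects (either may be `NULL`).
#' @param atlas the `roi_atlas`.
#' @param cn_ids control subject ids used to fit the ICV model; defaults
#'   to subjects with diagnosis `"CN"`.
#' @return List: `mri_adjusted`, `fdg_normalized`, `fdg_reference_scaled`,
#'   `icv_model`.
#' @export
preprocess_cohort <- function(meta, fdg, mri, atlas,
                              cn_ids = meta$subject_id[meta$diagnosis == "CN"]) {
  out <- list(mri_adjusted = NULL, fdg_normalized = NULL,
              fdg_reference_scaled = NULL, icv_model = NULL)
  if (!is.null(mri)) {
    cn_present <- intersect(cn_ids, subject_ids(mri))
    out$icv_model <- fit_icv_model(subset_subjects(mri, cn_present), meta)
    out$mri_adjusted <- apply_icv_adjustment(mri, meta, out$icv_model)
  }
  if (!is.null(fdg)) {
    out$fdg_normalized <- normalize_global_mean(fdg, atlas)
    out$fdg_reference_scaled <- scale_by_reference(fdg, atlas)
  }
  out
}

#' Expected cross-modality class agreement under the generator
#'
#' Closed-form expectation of the fraction of patients whose MRI template
#' matches their FDG template under the generator's mixing rule: a
#' patient's MRI template equals the FDG one with probability
#' `concordance` and is otherwise re-drawn from the prevalence
#' distribution, so the expected matching fraction is
#' `concordance + (1 - concordance) * sum(prevalence^2)`.
#'
#' @param concordance coupling probability in [0, 1].
#' @param prevalences template prevalence vector (sums to 1).
#' @return Expected agreement as a percentage.
#' @export
expected_concordant_fraction <- function(concordance, prevalences) {
  stopifnot(concordance >= 0, concordance <= 1,
            abs(sum(prevalences) - 1) < 1e-8)
  100 * (concordance + (1 - concordance) * sum(prevalences^2))
}
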