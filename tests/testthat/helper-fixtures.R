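# Small in-code fixtures shared across test files.

# 6-region toy atlas: hippocampus + amygdala (limbic), two association
# cortices, one primary cortex, pons reference
toy_atlas <- function() {
  roi_atlas(
    region_id = c("hippocampus", "amygdala", "ctx_assoc_a", "ctx_assoc_b",
                  "ctx_primary", "pons"),
    tissue_class = c("subcortical", "subcortical", "cortical", "cortical",
                     "cortical", "subcortical"),
    pattern_class = c("limbic", "limbic", "cortical-association",
                      "cortical-association", "other", "other"),
    is_hippocampus = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_reference = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
}

toy_matrix <- function(values, modality = "MRI",
                       units = if (modality == "MRI") "mm3" else "SUVR",
                       state = "raw") {
  roi_matrix(values, modality = modality, units = units, state = state)
}

# wrap an existing matrix's numeric values in an arbitrary analysis state
# (tests construct post-preprocessing inputs directly)
as_state <- function(values, modality, state) {
  units <- switch(state, "icv-adjusted" = "mm3",
                  "global-normalized" = "dimensionless",
                  "w-score" = "w-score", "SUVR")
  m <- roi_matrix(abs(values) + 1, modality = modality, units = units,
                  state = "raw")
  m$values <- values
  m$units <- units
  m$state <- state
  m
}

toy_meta <- function(n, diagnosis = "CN", seed = 1) {
  set.seed(seed)
  subject_meta(data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    diagnosis = rep_len(diagnosis, n),
    age = stats::rnorm(n, 74, 7),
    sex = sample(c("F", "M"), n, replace = TRUE),
    education = stats::rnorm(n, 16, 3),
    apoe4_carrier = stats::runif(n) < 0.3,
    icv = stats::rnorm(n, 1.5e6, 1.2e5),
    amyloid_status = ifelse(rep_len(diagnosis, n) == "CN",
                            "negative", "positive"),
    stringsAsFactors = FALSE))
}

# generate + preprocess a default synthetic cohort, returning the pieces
# most tests need
prep_cohort <- function(seed = 1, cfg = generator_config(seed = seed), ...) {
  atlas <- default_atlas()
  coh <- generate_cohort(cfg, atlas = atlas, ...)
  pre <- preprocess_cohort(coh$meta, coh$fdg, coh$mri, atlas)
  part <- select_analysis_sample(coh$meta)
  list(cohort = coh, pre = pre, atlas = atlas,
       ad_ids = part$subject_id[part$analysis_group == "AD_abeta_pos"],
       cn_ids = part$subject_id[part$analysis_group == "CN_abeta_neg"])
}

random_labeled_points <- function(n, d = 2, k = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d)
  labels <- sample(rep_len(seq_len(k), n))
  list(X = X, labels = labels)
}

# well-separated Gaussian blobs with known assignment
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(stats::rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  rownames(X) <- sprintf("b%03d", seq_len(nrow(X)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}
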