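#' Corticolimbic subtype template
#'
#' A template describes one planted spatial pattern of neurodegeneration as
#' mean shifts, in units of the control-group residual SD, applied to the
#' atlas pattern classes (negative values mean lower volume or uptake, i.e.
#' neurodegeneration). Per-region overrides take precedence over the class
#' effects.
#'
#' @param name template label.
#' @param limbic,cortical_association,other mean shift (control-SD units)
#'   for regions of the corresponding `pattern_class`.
#' @param region_effects optional named numeric vector of per-region shifts
#'   overriding the class effects.
#' @param severity_scale multiplier applied to all shifts (> 0).
#' @param prevalence proportion of the patient group drawn from this
#'   template.
#' @return A `subtype_template` list.
#' @export
subtype_template <- function(name, limbic = 0, cortical_association = 0,
                             other = 0, region_effects = NULL,
                             severity_scale = 1, prevalence) {
  stopifnot(severity_scale > 0, prevalence >= 0)
  structure(list(name = name,
                 class_effects = c("limbic" = limbic,
                                   "cortical-association" = cortical_association,
                                   "other" = other),
                 region_effects = region_effects,
                 severity_scale = severity_scale,
                 prevalence = prevalence),
            class = "subtype_template")
}

#' Default planted subtype templates
#'
#' Four corticolimbic patterns per modality, with effect magnitudes in the
#' 0.1-3.2 control-SD range seen in severe disease.
#'
#' For MRI (volumes): limbic-predominant (strong medial-temporal, mild
#' cortical atrophy), cortical-predominant (the reverse), diffuse (strong
#' widespread atrophy) and minimal (near-normal) — volumes carry absolute
#' severity, so a minimal/diffuse axis is identifiable.
#'
#' For FDG (uptake): global-mean intensity normalization removes each
#' subject's uniform severity component, so only pattern *shape*
#' distinguishes uptake subtypes. The FDG set therefore uses four
#' shape-distinct patterns — limbic-predominant, cortical-predominant, a
#' frontal-accented limbic variant and a posterior-accented cortical
#' variant — mirroring the corticolimbic variants reported for
#' hypometabolism.
#'
#' All pairs of templates within a set differ by at least 1.5 control SDs
#' in the region classes that distinguish them (for FDG, after removal of
#' the uniform component).
#'
#' @param modality `"MRI"` or `"FDG"`.
#' @return List of four [subtype_template()]s with prevalences
#'   (0.35, 0.30, 0.20, 0.15).
#' @export
default_templates <- function(modality = c("MRI", "FDG")) {
  modality <- match.arg(modality)
  common <- list(
    subtype_template("Limbic Predominant", limbic = -3.0,
                     cortical_association = -0.5, other = -0.3,
                     prevalence = 0.35),
    subtype_template("Cortical Predominant", limbic = -0.5,
                     cortical_association = -2.5, other = -0.3,
                     prevalence = 0.30))
  if (modality == "MRI") {
    c(common, list(
      subtype_template("Diffuse", limbic = -3.0, cortical_association = -2.0,
                       other = -2.0, prevalence = 0.20),
      subtype_template("Minimal", limbic = -0.1, cortical_association = -0.1,
                       other = -0.1, prevalence = 0.15)))
  } else {
    frontal <- c("superiorfrontal", "rostralmiddlefrontal",
                 "caudalmiddlefrontal", "frontalpole", "lateralorbitofrontal",
                 "medialorbitofrontal", "parsopercularis", "parsorbitalis",
                 "parstriangularis")
    posterior <- c("lateraloccipital", "lingual", "precuneus",
                   "superiorparietal", "inferiorparietal", "supramarginal",
                   "posteriorcingulate", "cuneus", "pericalcarine")
    c(common, list(
      subtype_template("Limbic Predominant frontal", limbic = -2.2,
                       cortical_association = -0.5, other = -0.3,
                       region_effects = stats::setNames(
                         rep(-3.2, length(frontal)), frontal),
                       prevalence = 0.20),
      subtype_template("Cortical Predominant posterior", limbic = -0.5,
                       cortical_association = -0.5, other = -0.3,
                       region_effects = stats::setNames(
                         rep(-3.2, length(posterior)), posterior),
                       prevalence = 0.15)))
  }
}

#' Synthetic cohort generator configuration
#'
#' Controls cohort sizes, covariate distributions and effect sizes, the
#' ICV-volume coupling, the two noise components, and the cross-modality
#' template concordance. Covariate effects are expressed in units of the
#' region residual SD per natural covariate unit, so their contribution to
#' the control-group variance stays interpretable. `icv_slope` is a
#' dimensionless elasticity: a region's expected volume changes by
#' `icv_slope` percent per percent ICV (0 removes the coupling).
#'
#' @param n_cn,n_ad group sizes.
#' @param concordance probability that a patient's MRI template equals its
#'   FDG template; otherwise the MRI template is re-drawn from the
#'   prevalence distribution.
#' @param covariate_effects named list per modality with elements `age`,
#'   `sex`, `education`, `apoe4` (residual-SD units per year, per male sex,
#'   per year, per carrier).
#' @param icv_slope ICV elasticity of regional volumes (MRI only).
#' @param global_scale_sd SD of the log-normal per-subject multiplicative
#'   uptake factor (FDG only); gives global-mean normalization real work.
#' @param residual_sd_frac region-level Gaussian noise SD as a fraction of
#'   the region baseline.
#' @param age_mean,age_sd,edu_mean,edu_sd,icv_mean,icv_sd,icv_sex_offset
#'   covariate distribution parameters (years, years, mm3).
#' @param apoe4_p_cn,apoe4_p_ad APOE e4 carrier probabilities.
#' @param seed integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cn = 176, n_ad = 180, concordance = 0.75,
                             covariate_effects = list(
                               FDG = list(age = -0.02, sex = 0.10,
                                          education = 0.005, apoe4 = -0.10),
                               MRI = list(age = -0.03, sex = 0.15,
                                          education = 0.005, apoe4 = -0.10)),
                             icv_slope = 0.6, global_scale_sd = 0.15,
                             residual_sd_frac = 0.06,
                             age_mean = 74, age_sd = 7,
                             edu_mean = 16, edu_sd = 3,
                             icv_mean = 1.5e6, icv_sd = 1.2e5,
                             icv_sex_offset = 1e5,
                             apoe4_p_cn = 0.2, apoe4_p_ad = 0.6,
                             seed = 1L) {
  stopifnot(n_cn >= 0, n_ad >= 0, concordance >= 0, concordance <= 1,
            global_scale_sd >= 0, residual_sd_frac >= 0, icv_slope >= 0)
  structure(as.list(environment()), class = "generator_config")
}

# deterministic per-region baselines: cortical regions larger than
# subcortical for volumes; uptake baselines near typical SUVR magnitudes
region_baselines <- function(atlas, modality) {
  if (modality == "MRI") {
    base <- ifelse(atlas$tissue_class == "cortical", 6000, 3200)
    base[atlas$is_hippocampus] <- 3600
    base[atlas$is_reference] <- 12000
  } else {
    base <- ifelse(atlas$tissue_class == "cortical", 1.45, 1.20)
    base[atlas$is_hippocampus] <- 1.25
    base[atlas$is_reference] <- 1.00
  }
  stats::setNames(base, atlas$region_id)
}

template_shift_matrix <- function(templates, atlas) {
  shifts <- vapply(templates, function(t) {
    s <- t$class_effects[atlas$pattern_class]
    if (!is.null(t$region_effects)) {
      idx <- match(names(t$region_effects), atlas$region_id)
      if (anyNA(idx))
        stop("template region override not in atlas: ",
             paste(names(t$region_effects)[is.na(idx)], collapse = ", "))
      s[idx] <- t$region_effects
    }
    s[atlas$is_reference] <- 0  # reference regions are spared by construction
    s * t$severity_scale
  }, numeric(nrow(atlas)))
  rownames(shifts) <- atlas$region_id
  shifts
}

#' Generate a synthetic two-modality cohort with planted subtypes
#'
#' Simulates a cognitively normal control group and a patient group whose
#' regional values follow planted corticolimbic templates in both
#' modalities. Control values are baseline plus covariate effects plus
#' Gaussian region noise; volumes additionally scale with intracranial
#' volume; uptake rows additionally carry a log-normal per-subject global
#' factor. Each patient's FDG template is drawn by prevalence; the MRI
#' template matches it with probability `cfg$concordance` and is otherwise
#' re-drawn. Ground-truth labels for both modalities are returned.
#'
#' @param cfg a [generator_config()].
#' @param templates_fdg,templates_mri lists of [subtype_template()]s; the
#'   two lists must have equal length and matching names for the
#'   concordance coupling to be meaningful.
#' @param atlas a `roi_atlas`.
#' @return A list with `meta` (`subject_meta`), `fdg` and `mri` (raw
#'   `roi_matrix` objects), and `truth` (data.frame with `subject_id`,
#'   `template_fdg`, `template_mri`; `"none"` for controls).
#' @export
generate_cohort <- function(cfg = generator_config(),
                            templates_fdg = default_templates("FDG"),
                            templates_mri = default_templates("MRI"),
                            atlas = default_atlas()) {
  prev_f <- vapply(templates_fdg, `[[`, numeric(1), "prevalence")
  prev_m <- vapply(templates_mri, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev_f) - 1) > 1e-8 || abs(sum(prev_m) - 1) > 1e-8)
    stop("template prevalences must sum to 1")
  if (length(templates_fdg) != length(templates_mri))
    stop("template lists must have equal length across modalities")
  if (!any(atlas$pattern_class == "limbic") ||
      !any(atlas$pattern_class == "cortical-association"))
    stop("degenerate atlas: needs limbic and cortical-association regions")
  set.seed(cfg$seed)

  n <- cfg$n_cn + cfg$n_ad
  diagnosis <- c(rep("CN", cfg$n_cn), rep("AD", cfg$n_ad))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  education <- pmax(6, stats::rnorm(n, cfg$edu_mean, cfg$edu_sd))
  apoe4 <- stats::rbinom(n, 1,
                         ifelse(diagnosis == "AD", cfg$apoe4_p_ad,
                                cfg$apoe4_p_cn)) == 1
  icv <- stats::rnorm(n, cfg$icv_mean + cfg$icv_sex_offset * (sex == "M"),
                      cfg$icv_sd)
  meta <- subject_meta(data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    diagnosis = diagnosis, age = age, sex = sex, education = education,
    apoe4_carrier = apoe4, icv = icv,
    amyloid_status = ifelse(diagnosis == "CN", "negative", "positive"),
    wmh_volume = stats::rlnorm(n, log(5), 0.8),
    days_between_scans = stats::rpois(n, 30),
    stringsAsFactors = FALSE))

  names_f <- vapply(templates_fdg, `[[`, character(1), "name")
  names_m <- vapply(templates_mri, `[[`, character(1), "name")
  idx_f <- sample.int(length(templates_fdg), cfg$n_ad, replace = TRUE,
                      prob = prev_f)
  match_draw <- stats::runif(cfg$n_ad) < cfg$concordance
  idx_m <- ifelse(match_draw, idx_f,
                  sample.int(length(templates_mri), cfg$n_ad, replace = TRUE,
                             prob = prev_m))
  truth <- data.frame(
    subject_id = meta$subject_id,
    template_fdg = c(rep("none", cfg$n_cn), names_f[idx_f]),
    template_mri = c(rep("none", cfg$n_cn), names_m[idx_m]),
    stringsAsFactors = FALSE)

  simulate_modality <- function(modality, templates, template_idx) {
    base <- region_baselines(atlas, modality)
    res_sd <- cfg$residual_sd_frac * base
    eff <- cfg$covariate_effects[[modality]]
    cov_shift <- outer(eff$age * (age - cfg$age_mean) +
                       eff$sex * (sex == "M") +
                       eff$education * (education - cfg$edu_mean) +
                       eff$apoe4 * apoe4, res_sd)
    mu <- matrix(base, n, length(base), byrow = TRUE) + cov_shift
    if (modality == "MRI" && cfg$icv_slope > 0) {
      mu <- mu + outer(icv - cfg$icv_mean,
                       cfg$icv_slope * base / cfg$icv_mean)
    }
    shifts <- template_shift_matrix(templates, atlas)
    ad_rows <- which(diagnosis == "AD")
    mu[ad_rows, ] <- mu[ad_rows, ] +
      t(shifts[, template_idx, drop = FALSE] * res_sd)
    vals <- mu + matrix(stats::rnorm(n * length(base), 0, 1), n) *
      matrix(res_sd, n, length(base), byrow = TRUE)
    if (modality == "FDG" && cfg$global_scale_sd > 0)
      vals <- vals * exp(stats::rnorm(n, 0, cfg$global_scale_sd))
    vals <- pmax(vals, 0.05 * matrix(base, n, length(base), byrow = TRUE))
    dimnames(vals) <- list(meta$subject_id, atlas$region_id)
    roi_matrix(vals, modality = modality,
               units = if (modality == "MRI") "mm3" else "SUVR",
               state = "raw")
  }

  list(meta = meta,
       fdg = simulate_modality("FDG", templates_fdg, idx_f),
       mri = simulate_modality("MRI", templates_mri, idx_m),
       truth = truth)
}

#' Realized planted effect sizes
#'
#' Measures, per region, the realized standardized shift of one planted
#' template relative to controls: (template-group mean - CN mean) / CN SD.
#' Used to confirm that the generator honors its `region_effects`.
#'
#' @param values a `roi_matrix` (any state).
#' @param meta the cohort metadata.
#' @param truth the truth table returned by [generate_cohort()].
#' @param template template name to evaluate.
#' @param modality `"FDG"` or `"MRI"` (which truth column to use);
#'   defaults to the modality of `values`.
#' @return Named numeric vector of realized effects per region.
#' @export
planted_effect_check <- function(values, meta, truth, template,
                                 modality = values$modality) {
  col <- paste0("template_", tolower(modality))
  lab <- truth[[col]][match(subject_ids(values), truth$subject_id)]
  dx <- meta$diagnosis[match(subject_ids(values), meta$subject_id)]
  in_template <- !is.na(lab) & lab == template
  in_cn <- dx == "CN"
  if (sum(in_template) < 2 || sum(in_cn) < 2)
    stop("need at least 2 subjects per compared group")
  cn <- values$values[in_cn, , drop = FALSE]
  tm <- values$values[in_template, , drop = FALSE]
  (colMeans(tm) - colMeans(cn)) / apply(cn, 2, stats::sd)
}
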