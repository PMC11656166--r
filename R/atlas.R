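#' Region-of-interest atlas
#'
#' An ROI atlas is a data frame with one row per region carrying the
#' metadata every downstream stage needs: which regions are limbic versus
#' cortical-association (driving the corticolimbic pattern definitions and
#' the hippocampus-to-cortex ratio), which region is the hippocampus, and
#' which regions serve as the uptake reference (pons-like) for
#' reference-region scaling.
#'
#' @param region_id character, unique short keys.
#' @param region_name character, free-text names (defaults to `region_id`).
#' @param hemisphere_scope one of `"bilateral-merged"`, `"left"`, `"right"`
#'   per region.
#' @param tissue_class `"cortical"` or `"subcortical"` per region.
#' @param pattern_class `"limbic"`, `"cortical-association"` or `"other"`
#'   per region.
#' @param is_hippocampus logical per region.
#' @param is_reference logical per region; reference regions are used only
#'   for uptake scaling and are excluded from pattern statistics.
#'
#' @return A `data.frame` of class `roi_atlas`.
#' @export
roi_atlas <- function(region_id, region_name = region_id,
                      hemisphere_scope = "bilateral-merged",
                      tissue_class, pattern_class,
                      is_hippocampus = FALSE, is_reference = FALSE) {
  n <- length(region_id)
  atlas <- data.frame(
    region_id = as.character(region_id),
    region_name = rep_len(as.character(region_name), n),
    hemisphere_scope = rep_len(hemisphere_scope, n),
    tissue_class = rep_len(tissue_class, n),
    pattern_class = rep_len(pattern_class, n),
    is_hippocampus = rep_len(is_hippocampus, n),
    is_reference = rep_len(is_reference, n),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("roi_atlas", "data.frame")
  validate_roi_atlas(atlas)
}

validate_roi_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  req <- c("region_id", "region_name", "hemisphere_scope", "tissue_class",
           "pattern_class", "is_hippocampus", "is_reference")
  missing_cols <- setdiff(req, names(atlas))
  if (length(missing_cols))
    stop("atlas is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atlas$region_id))
    stop("duplicated region_id in atlas: ",
         paste(unique(atlas$region_id[duplicated(atlas$region_id)]),
               collapse = ", "))
  if (!any(atlas$is_hippocampus))
    stop("atlas must contain at least one hippocampus region")
  if (!any(atlas$is_reference))
    stop("atlas must contain at least one reference region")
  if (any(atlas$is_reference & atlas$is_hippocampus))
    stop("a reference region cannot be the hippocampus")
  if (!any(atlas$pattern_class == "cortical-association"))
    stop("atlas must contain at least one cortical-association region")
  bad_scope <- setdiff(atlas$hemisphere_scope,
                       c("bilateral-merged", "left", "right"))
  if (length(bad_scope))
    stop("unknown hemisphere_scope: ", paste(bad_scope, collapse = ", "))
  bad_pat <- setdiff(atlas$pattern_class,
                     c("limbic", "cortical-association", "other"))
  if (length(bad_pat))
    stop("unknown pattern_class: ", paste(bad_pat, collapse = ", "))
  atlas
}

#' Default bilateral-merged corticolimbic atlas
#'
#' Builds the package's default atlas: 34 cortical regions following the
#' Desikan-Killiany parcellation, 7 subcortical grey-matter structures and
#' the pons as uptake reference region, all hemisphere-merged. The limbic
#' set comprises the hippocampus, amygdala, entorhinal and parahippocampal
#' cortex, temporal pole and isthmus cingulate; primary sensorimotor and
#' early visual regions are classed `"other"`; the remaining neocortex is
#' `"cortical-association"`.
#'
#' @return A `roi_atlas` with 42 regions.
#' @export
#' @examples
#' atlas <- default_atlas()
#' table(atlas$pattern_class)
default_atlas <- function() {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal")
  subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                   "hippocampus", "amygdala", "accumbens")
  limbic <- c("hippocampus", "amygdala", "entorhinal", "parahippocampal",
              "temporalpole", "isthmuscingulate")
  primary <- c("precentral", "postcentral", "paracentral", "pericalcarine",
               "cuneus", "transversetemporal")
  ids <- c(cortical, subcortical, "pons")
  tissue <- c(rep("cortical", length(cortical)),
              rep("subcortical", length(subcortical) + 1L))
  pattern <- ifelse(ids %in% limbic, "limbic",
                    ifelse(ids %in% cortical & !(ids %in% primary),
                           "cortical-association", "other"))
  roi_atlas(
    region_id = ids,
    tissue_class = tissue,
    pattern_class = pattern,
    is_hippocampus = ids == "hippocampus",
    is_reference = ids == "pons"
  )
}

# region id sets used throughout: reference regions are excluded from every
# grey-matter summary
atlas_regions <- function(atlas, what = c("all", "non-reference", "reference",
                                          "hippocampus", "cortical-association",
                                          "limbic", "cortical")) {
  what <- match.arg(what)
  keep <- switch(what,
    "all" = rep(TRUE, nrow(atlas)),
    "non-reference" = !atlas$is_reference,
    "reference" = atlas$is_reference,
    "hippocampus" = atlas$is_hippocampus,
    "cortical-association" = atlas$pattern_class == "cortical-association",
    "limbic" = atlas$pattern_class == "limbic",
    "cortical" = atlas$tissue_class == "cortical" & !atlas$is_reference
  )
  atlas$region_id[keep]
}
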