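#' Subject metadata table
#'
#' Validates a per-subject covariate table. Required columns: `subject_id`,
#' `diagnosis` (CN/MCI/AD), `age` (years), `sex` (F/M), `education` (years),
#' `apoe4_carrier` (logical), `icv` (mm3), `amyloid_status`
#' (positive/negative/NA). Optional: `wmh_volume`, `days_between_scans`.
#'
#' @param meta a data.frame.
#' @return The validated data.frame, classed `subject_meta`.
#' @export
subject_meta <- function(meta) {
  req <- c("subject_id", "diagnosis", "age", "sex", "education",
           "apoe4_carrier", "icv", "amyloid_status")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  meta$subject_id <- as.character(meta$subject_id)
  if (anyDuplicated(meta$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(meta$subject_id[duplicated(meta$subject_id)]),
               collapse = ", "))
  bad_dx <- setdiff(meta$diagnosis, c("CN", "MCI", "AD"))
  if (length(bad_dx)) stop("unknown diagnosis: ", paste(bad_dx, collapse = ", "))
  bad_sex <- setdiff(meta$sex, c("F", "M"))
  if (length(bad_sex)) stop("unknown sex code: ", paste(bad_sex, collapse = ", "))
  for (v in c("age", "education", "icv")) {
    if (any(!is.na(meta[[v]]) & meta[[v]] <= 0))
      stop(v, " must be strictly positive")
  }
  meta$apoe4_carrier <- as.logical(meta$apoe4_carrier)
  if (!all(class(meta) == "data.frame"))
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  class(meta) <- c("subject_meta", "data.frame")
  meta
}

# full-precision decimal rendering so write -> read round-trips reproduce
# doubles bit for bit
fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(values, path) {
  chr <- matrix(fmt_num(values), nrow = nrow(values),
                dimnames = dimnames(values))
  df <- data.frame(subject_id = rownames(values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("matrix file lacks a subject_id column: ", path)
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids))
    stop("duplicated subject row in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[setdiff(names(df), "subject_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a cohort to delimited text files
#'
#' Writes metadata, the two modality matrices, the atlas, and (optionally)
#' ground-truth template labels as comma-delimited UTF-8 files with header
#' rows. Numeric matrix values are written at full precision so a
#' write/read round trip is exact.
#'
#' @param dir output directory (created if needed).
#' @param meta a `subject_meta` table.
#' @param fdg,mri `roi_matrix` objects (either may be `NULL`).
#' @param atlas a `roi_atlas`.
#' @param truth optional data.frame of per-subject template labels.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(dir, meta, fdg, mri, atlas, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(meta = file.path(dir, "meta.csv"),
             fdg = file.path(dir, "fdg.csv"),
             mri = file.path(dir, "mri.csv"),
             atlas = file.path(dir, "atlas.csv"))
  utils::write.csv(as.data.frame(meta), paths[["meta"]], row.names = FALSE)
  if (!is.null(fdg)) write_matrix_csv(fdg$values, paths[["fdg"]])
  if (!is.null(mri)) write_matrix_csv(mri$values, paths[["mri"]])
  utils::write.csv(as.data.frame(atlas), paths[["atlas"]], row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a cohort from delimited text files
#'
#' Reads the metadata, FDG and MRI regional matrices and the atlas, aligns
#' matrix rows to the metadata order and matrix columns to the atlas order,
#' and reports (then drops from that modality) subjects present in the
#' metadata but absent from a matrix.
#'
#' @param meta_path,fdg_path,mri_path,atlas_path file paths; `fdg_path` or
#'   `mri_path` may be `NULL` for a single-modality cohort.
#' @return A list with elements `meta`, `fdg`, `mri`, `atlas`.
#' @export
read_cohort <- function(meta_path, fdg_path, mri_path, atlas_path) {
  meta <- subject_meta(utils::read.csv(meta_path, stringsAsFactors = FALSE))
  atlas <- utils::read.csv(atlas_path, stringsAsFactors = FALSE)
  class(atlas) <- c("roi_atlas", "data.frame")
  atlas <- validate_roi_atlas(atlas)

  load_modality <- function(path, modality, units) {
    if (is.null(path)) return(NULL)
    m <- read_matrix_csv(path)
    unknown <- setdiff(colnames(m), atlas$region_id)
    if (length(unknown))
      stop("region(s) in ", basename(path), " absent from atlas: ",
           paste(unknown, collapse = ", "))
    missing_regions <- setdiff(atlas$region_id, colnames(m))
    if (length(missing_regions))
      stop("atlas region(s) missing from ", basename(path), ": ",
           paste(missing_regions, collapse = ", "))
    dropped <- setdiff(meta$subject_id, rownames(m))
    if (length(dropped))
      message(modality, ": dropping ", length(dropped),
              " subject(s) without regional data: ",
              paste(dropped, collapse = ", "))
    extra <- setdiff(rownames(m), meta$subject_id)
    if (length(extra))
      stop("subject(s) in ", basename(path), " absent from metadata: ",
           paste(extra, collapse = ", "))
    keep <- meta$subject_id[meta$subject_id %in% rownames(m)]
    roi_matrix(m[keep, atlas$region_id, drop = FALSE], modality = modality,
               units = units, state = "raw")
  }

  list(meta = meta,
       fdg = load_modality(fdg_path, "FDG", "SUVR"),
       mri = load_modality(mri_path, "MRI", "mm3"),
       atlas = atlas)
}

#' Partition a cohort into the analysis samples
#'
#' Applies the amyloid-based inclusion rule: AD and MCI subjects enter the
#' analysis only if amyloid positive; CN subjects only if amyloid negative;
#' everyone else (including subjects with missing amyloid status) is
#' excluded with a recorded reason. The partition is exhaustive and
#' disjoint.
#'
#' @param meta a `subject_meta` table.
#' @return `meta` with added columns `analysis_group` (one of
#'   `"AD_abeta_pos"`, `"MCI_abeta_pos"`, `"CN_abeta_neg"`, `"excluded"`)
#'   and `exclusion_reason`.
#' @export
select_analysis_sample <- function(meta) {
  grp <- rep("excluded", nrow(meta))
  reason <- rep(NA_character_, nrow(meta))
  amy <- meta$amyloid_status
  missing_amy <- is.na(amy) | amy == ""
  reason[missing_amy] <- "missing amyloid status"
  pos <- !missing_amy & amy == "positive"
  neg <- !missing_amy & amy == "negative"
  grp[meta$diagnosis == "AD" & pos] <- "AD_abeta_pos"
  grp[meta$diagnosis == "MCI" & pos] <- "MCI_abeta_pos"
  grp[meta$diagnosis == "CN" & neg] <- "CN_abeta_neg"
  mismatched <- grp == "excluded" & !missing_amy
  reason[mismatched] <- paste0(meta$diagnosis[mismatched],
                               " with amyloid-", amy[mismatched])
  if (any(missing_amy))
    message("excluded ", sum(missing_amy), " subject(s) with missing amyloid status")
  meta$analysis_group <- grp
  meta$exclusion_reason <- reason
  meta
}
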