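#' Regional value matrix for one modality
#'
#' A `roi_matrix` bundles a subjects x regions numeric matrix with the
#' modality it came from, its physical units, and a processing-state tag.
#' The state tag enforces the analysis ordering: clustering consumes
#' `"global-normalized"` uptake and `"icv-adjusted"` volumes, while w-score
#' brain maps consume `"reference-scaled"` uptake. States change only
#' through the preprocessing and w-score operations.
#'
#' @param values numeric matrix with subject ids as row names and region
#'   ids as column names.
#' @param modality `"FDG"` or `"MRI"`.
#' @param units `"SUVR"`, `"mm3"`, `"dimensionless"` or `"w-score"`.
#' @param state `"raw"`, `"global-normalized"`, `"reference-scaled"`,
#'   `"icv-adjusted"` or `"w-score"`.
#'
#' @return An object of class `roi_matrix`.
#' @export
roi_matrix <- function(values, modality = c("FDG", "MRI"),
                       units = c("SUVR", "mm3", "dimensionless", "w-score"),
                       state = c("raw", "global-normalized",
                                 "reference-scaled", "icv-adjusted",
                                 "w-score")) {
  modality <- match.arg(modality)
  units <- match.arg(units)
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("roi_matrix values need subject row names and region column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated subject ids in roi_matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated region ids in roi_matrix")
  if (!is.numeric(values)) stop("roi_matrix values must be numeric")
  if (anyNA(values)) stop("roi_matrix values must be complete (no NA)")
  if (state == "raw" && any(values <= 0))
    stop("raw regional values must be strictly positive")
  structure(list(values = values, modality = modality, units = units,
                 state = state),
            class = "roi_matrix")
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("<roi_matrix> %s [%s, %s]: %d subjects x %d regions\n",
              x$modality, x$units, x$state,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.roi_matrix <- function(x) dim(x$values)

subject_ids <- function(x) rownames(x$values)
region_ids <- function(x) colnames(x$values)

#' Restrict a regional matrix to a subject subset
#'
#' Row-subsets a `roi_matrix` (e.g. to the patient analysis sample)
#' preserving modality, units and processing state.
#'
#' @param x a `roi_matrix`.
#' @param ids subject ids to keep (order preserved).
#' @return A `roi_matrix` with the selected rows.
#' @export
subset_subjects <- function(x, ids) {
  missing_ids <- setdiff(ids, subject_ids(x))
  if (length(missing_ids))
    stop("subject(s) not in matrix: ", paste(missing_ids, collapse = ", "))
  x$values <- x$values[ids, , drop = FALSE]
  x
}

# internal: replace values/state without re-running positivity checks meant
# for raw inputs
set_state <- function(x, values, units = x$units, state) {
  x$values <- values
  x$units <- units
  x$state <- state
  x
}

require_state <- function(x, states, label = deparse(substitute(x))) {
  if (!x$state %in% states)
    stop(sprintf("%s must be in state %s, got '%s'", label,
                 paste(sQuote(states), collapse = " or "), x$state))
  invisible(x)
}
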