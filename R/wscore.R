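#' Fit the per-region w-score model on controls
#'
#' For every region, fits an ordinary least-squares regression of the
#' regional value on age, sex, education and APOE e4 carriership in the
#' cognitively normal group and stores the coefficients together with the
#' residual SD. W-scores are covariate-adjusted z-scores relative to this
#' normative fit. Covariates enter in natural units (years; 0/1 indicators
#' for male sex and carriership). A covariate with no variance in the
#' fitting sample (e.g. all controls the same sex) is dropped with a
#' warning.
#'
#' @param values_cn control-group `roi_matrix` in the state required for
#'   the downstream map (`"reference-scaled"` uptake or `"icv-adjusted"`
#'   volume; `"global-normalized"` also accepted).
#' @param meta_cn matching `subject_meta` rows.
#' @return A `wscore_model`: coefficients matrix (terms x regions),
#'   `residual_sd` per region, covariate names used, and `n`.
#' @export
fit_wscore_model <- function(values_cn, meta_cn) {
  require_state(values_cn, c("reference-scaled", "icv-adjusted",
                             "global-normalized"))
  meta_cn <- meta_cn[match(subject_ids(values_cn), meta_cn$subject_id), ]
  X <- wscore_design(meta_cn)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(col) stats::var(col) > 0))
  if (!all(keep)) {
    warning("dropping covariate(s) with no variance in controls: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1)
    stop("control sample too small for ", p - 1, " covariates")
  fit <- stats::lm.fit(X, values_cn$values)
  res <- as.matrix(fit$residuals)
  residual_sd <- sqrt(colSums(res^2) / (n - p))
  if (any(residual_sd < 1e-10))
    stop("degenerate fit: residual SD ~ 0 for region(s) ",
         paste(region_ids(values_cn)[residual_sd < 1e-10], collapse = ", "))
  structure(list(coefficients = as.matrix(fit$coefficients),
                 residual_sd = stats::setNames(residual_sd,
                                               region_ids(values_cn)),
                 terms = colnames(X), n = n, state = values_cn$state),
            class = "wscore_model")
}

wscore_design <- function(meta) {
  for (v in c("age", "sex", "education", "apoe4_carrier")) {
    if (anyNA(meta[[v]]))
      stop("missing covariate '", v, "' for subject(s) ",
           paste(meta$subject_id[is.na(meta[[v]])], collapse = ", "))
  }
  cbind("(Intercept)" = 1, age = meta$age, sex_male = as.numeric(meta$sex == "M"),
        education = meta$education, apoe4 = as.numeric(meta$apoe4_carrier))
}

#' Compute covariate-adjusted w-scores
#'
#' w = (observed - covariate-predicted) / residual SD, using the
#' control-fitted model. With `reverse = TRUE` (the default) the sign is
#' flipped so that higher w-scores mean greater neurodegeneration — lower
#' volume and lower uptake both map to positive w.
#'
#' @param values `roi_matrix` in the same state the model was fitted on.
#' @param meta matching `subject_meta` rows.
#' @param model a `wscore_model`.
#' @param reverse flip the sign so higher = more neurodegeneration.
#' @return A `"w-score"` `roi_matrix`.
#' @export
compute_wscores <- function(values, meta, model, reverse = TRUE) {
  if (!identical(region_ids(values), names(model$residual_sd)))
    stop("model regions do not match matrix regions")
  meta <- meta[match(subject_ids(values), meta$subject_id), ]
  X <- wscore_design(meta)[, model$terms, drop = FALSE]
  pred <- X %*% model$coefficients
  w <- sweep(values$values - pred, 2, model$residual_sd, "/")
  if (reverse) w <- -w
  out <- set_state(values, w, units = "w-score", state = "w-score")
  attr(out, "reversed") <- reverse
  out
}

#' Mean neurodegeneration map per subtype
#'
#' Averages the w-scores of each labeled subtype per region, yielding the
#' plottable long-format table behind subtype brain maps.
#'
#' @param w a `"w-score"` `roi_matrix`.
#' @param labels named character vector (names = subject ids) or vector
#'   aligned to the matrix rows.
#' @return data.frame with columns `subtype`, `region_id`, `mean_w`, `n`.
#' @export
subtype_mean_map <- function(w, labels) {
  require_state(w, "w-score")
  labels <- align_labels(labels, subject_ids(w))
  present <- !is.na(labels)
  if (!all(present)) {
    warning("dropping ", sum(!present), " unlabeled subject(s) from map")
  }
  groups <- split(which(present), labels[present])
  groups <- groups[lengths(groups) > 0]
  do.call(rbind, lapply(names(groups), function(g) {
    rows <- groups[[g]]
    data.frame(subtype = g, region_id = region_ids(w),
               mean_w = colMeans(w$values[rows, , drop = FALSE]),
               n = length(rows), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

# accept either a vector named by subject id or one aligned by position
align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    out <- labels[match(ids, names(labels))]
  } else {
    if (length(labels) != length(ids))
      stop("labels must be named by subject id or aligned to the matrix rows")
    out <- labels
  }
  stats::setNames(as.character(out), ids)
}
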