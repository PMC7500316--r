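#' Construct a morphometry cohort
#'
#' A cohort bundles a subjects-by-regions matrix of morphometric values
#' (e.g. regional gray matter volumes) with per-subject nuisance covariates
#' (age in years, sex coded 0/1, total intracranial volume) and a group
#' label. Correlation across subjects needs at least 3 residual
#' observations, so cohorts with fewer than 3 subjects are rejected.
#'
#' @param values numeric matrix, subjects in rows, regions in columns.
#' @param covariates data frame with columns `subject`, `age`, `sex`, `tiv`,
#'   one row per subject, aligned with `values`.
#' @param group_label character scalar.
#' @param region_names unique region labels; default taken from `values`
#'   column names.
#' @return A `morph_cohort` object.
#' @export
new_morph_cohort <- function(values, covariates, group_label,
                             region_names = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must not contain missing or non-finite entries",
         call. = FALSE)
  }
  if (nrow(values) < 3) {
    stop("a cohort needs at least 3 subjects", call. = FALSE)
  }
  if (is.null(region_names) || length(region_names) != ncol(values)) {
    stop("`region_names` must match the number of regions", call. = FALSE)
  }
  if (anyDuplicated(region_names)) {
    stop("`region_names` must be unique", call. = FALSE)
  }
  stopifnot(is.data.frame(covariates),
            all(c("subject", "age", "sex", "tiv") %in% names(covariates)),
            nrow(covariates) == nrow(values))
  colnames(values) <- region_names
  if (is.null(rownames(values))) {
    rownames(values) <- as.character(covariates$subject)
  }
  structure(
    list(values = values,
         covariates = covariates,
         group_label = as.character(group_label),
         region_names = as.character(region_names)),
    class = "morph_cohort"
  )
}

#' @export
print.morph_cohort <- function(x, ...) {
  cat(sprintf("<morph_cohort> group '%s': %d subjects x %d regions\n",
              x$group_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.morph_cohort <- function(x) dim(x$values)
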