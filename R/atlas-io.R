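#' The 90-region AAL atlas table
#'
#' Returns the automated anatomical labeling (AAL) parcellation table used
#' as the default node set for structural covariance networks: the 90
#' cerebral regions (45 bilateral structures, cerebellum excluded), with
#' hemisphere-suffixed abbreviations (\code{.L}/\code{.R}) and full names.
#'
#' @return A data frame with columns \code{region_index} (1..90),
#'   \code{abbreviation} and \code{full_name}.
#' @export
#' @examples
#' head(aal90_atlas())
aal90_atlas <- function() {
  path <- system.file("extdata", "aal90_regions.csv", package = "scovnet",
                      mustWork = TRUE)
  read_atlas(path)
}

#' Read an atlas table from CSV
#'
#' An atlas CSV must have columns \code{region_index}, \code{abbreviation}
#' and \code{full_name}; any parcellation size is accepted, so networks are
#' not tied to the 90-node default.
#'
#' @param path path to the atlas CSV.
#' @return A validated atlas data frame.
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_index", "abbreviation", "full_name")
  missing_cols <- setdiff(need, names(atlas))
  if (length(missing_cols) > 0) {
    stop("atlas file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(atlas$abbreviation)) {
    stop("atlas abbreviations must be unique", call. = FALSE)
  }
  atlas[order(atlas$region_index), need]
}

#' Read a morphometry cohort from CSV files
#'
#' Reads a subjects-by-regions table of morphometric values (first column
#' \code{subject}, remaining columns named by atlas abbreviations) together
#' with a per-subject covariates table (\code{subject}, \code{age},
#' \code{sex}, \code{tiv}). Region columns are reordered to canonical atlas
#' order; subjects are aligned across the two files by id.
#'
#' Sex must be coded 0/1; any other encoding is refused rather than
#' guessed at.
#'
#' @param values_path CSV of regional values, one row per subject.
#' @param covariates_path CSV of covariates, one row per subject.
#' @param group_label label attached to the cohort (e.g. "patients").
#' @param atlas atlas table; defaults to [aal90_atlas()]. Pass a custom
#'   atlas (see [read_atlas()]) for other parcellations.
#' @return A `morph_cohort` object.
#' @export
read_cohort <- function(values_path, covariates_path, group_label,
                        atlas = aal90_atlas()) {
  vals <- utils::read.csv(values_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"subject" %in% names(vals)) {
    stop("values file must have a `subject` column", call. = FALSE)
  }
  region_cols <- setdiff(names(vals), "subject")
  unknown <- setdiff(region_cols, atlas$abbreviation)
  if (length(unknown) > 0) {
    stop("unknown region name(s) in values file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_regions <- setdiff(atlas$abbreviation, region_cols)
  if (length(missing_regions) > 0) {
    stop("values file is missing region(s): ",
         paste(utils::head(missing_regions, 5), collapse = ", "),
         if (length(missing_regions) > 5) ", ..." else "", call. = FALSE)
  }
  subjects <- as.character(vals$subject)
  values <- as.matrix(vals[, atlas$abbreviation, drop = FALSE])
  if (!is.numeric(values) || any(is.na(values)) || any(!is.finite(values))) {
    bad <- which(is.na(values) | !is.finite(suppressWarnings(values * 1)),
                 arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- matrix(c(1L, 1L), 1)
    stop(sprintf(
      "non-numeric or missing value at subject '%s', region '%s'",
      subjects[bad[1, 1]], colnames(values)[bad[1, 2]]), call. = FALSE)
  }
  rownames(values) <- subjects

  cov <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
  need <- c("subject", "age", "sex", "tiv")
  missing_cols <- setdiff(need, names(cov))
  if (length(missing_cols) > 0) {
    stop("covariates file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cov$subject <- as.character(cov$subject)
  missing_subj <- setdiff(subjects, cov$subject)
  if (length(missing_subj) > 0) {
    stop("covariates missing for subject(s): ",
         paste(missing_subj, collapse = ", "), call. = FALSE)
  }
  cov <- cov[match(subjects, cov$subject), need]
  if (any(is.na(cov$age)) || any(is.na(cov$sex)) || any(is.na(cov$tiv))) {
    stop("missing covariate values", call. = FALSE)
  }
  if (!all(cov$sex %in% c(0, 1))) {
    stop("`sex` must be coded 0/1; found: ",
         paste(utils::head(unique(cov$sex[!cov$sex %in% c(0, 1)])),
               collapse = ", "), call. = FALSE)
  }
  new_morph_cohort(values = values, covariates = cov,
                   group_label = group_label,
                   region_names = atlas$abbreviation)
}

#' Write a cohort to CSV files
#'
#' Writes the regional values and covariates as two CSV files in the layout
#' accepted by [read_cohort()].
#'
#' @param cohort a `morph_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; defaults to the group label.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = cohort$group_label) {
  stopifnot(inherits(cohort, "morph_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  values_path <- file.path(dir, paste0(prefix, "_values.csv"))
  cov_path <- file.path(dir, paste0(prefix, "_covariates.csv"))
  df <- data.frame(subject = rownames(cohort$values),
                   cohort$values, check.names = FALSE)
  utils::write.csv(df, values_path, row.names = FALSE)
  utils::write.csv(cohort$covariates, cov_path, row.names = FALSE)
  invisible(c(values = values_path, covariates = cov_path))
}
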