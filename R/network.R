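# Group-level covariance network construction: nuisance regression,
# Pearson interregional correlation, and density thresholding on a grid.

#' Density grid for network thresholding
#'
#' The conventional thresholding range for binary structural covariance
#' networks: densities from 0.10 to 0.50 in steps of 0.02. The lower end is
#' meant to keep the group networks fully connected, the upper end to stop
#' short of densities where binary brain graphs approach randomness (above
#' 50% connections structural networks are considered non-biological), see
#' [validate_density_grid()].
#'
#' @param start,stop,step grid limits and spacing; `0 < start <= stop < 1`.
#' @return A numeric vector of densities with class `scov_grid`.
#' @export
density_grid <- function(start = 0.10, stop = 0.50, step = 0.02) {
  if (!(start > 0 && start <= stop && stop < 1 && step > 0)) {
    stop("need 0 < start <= stop < 1 and step > 0", call. = FALSE)
  }
  g <- seq(start, stop, by = step)
  g <- round(g, 10)
  structure(g, class = "scov_grid", start = start, stop = stop, step = step)
}

#' Remove nuisance covariates from regional values
#'
#' Per region, ordinary least squares of the regional values on an
#' intercept, age, sex and total intracranial volume, fitted within the
#' given group only; the residuals (zero mean per region) are what enter
#' the interregional correlation.
#'
#' @param cohort a `morph_cohort`.
#' @return Numeric matrix of residuals, subjects by regions.
#' @export
residualize <- function(cohort) {
  stopifnot(inherits(cohort, "morph_cohort"))
  X <- stats::model.matrix(~ age + sex + tiv, data = cohort$covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear nuisance covariates: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qrX, cohort$values)
  dimnames(res) <- dimnames(cohort$values)
  res
}

#' Interregional Pearson correlation matrix
#'
#' Pearson correlation between every pair of regions across subjects.
#' The diagonal is set to zero: self-correlations are not edges.
#'
#' @param residuals subjects-by-regions matrix (from [residualize()], or
#'   raw values if no nuisance regression is wanted).
#' @return Symmetric correlation matrix with zero diagonal.
#' @export
correlation_matrix <- function(residuals) {
  if (nrow(residuals) < 3) {
    stop("correlation needs at least 3 subjects", call. = FALSE)
  }
  sds <- apply(residuals, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(colnames(residuals)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(residuals)
  diag(r) <- 0
  r
}

#' Threshold a correlation matrix at a target density
#'
#' Keeps the `K = round(density * N(N-1)/2)` strongest edges and
#' binarizes. By default edges are ranked by signed correlation (strongest
#' positive co-variation enters first, the usual convention for structural
#' covariance edges); `rank_by = "abs"` ranks by magnitude instead. Ties at
#' the cutoff are broken by descending `|r|` and then by lexicographic node
#' pair order, so the edge set is fully deterministic, and edge sets are
#' nested along any increasing sequence of densities.
#'
#' @param r symmetric correlation matrix (diagonal ignored).
#' @param density target edge fraction in (0, 1].
#' @param rank_by `"signed"` (default) or `"abs"`.
#' @return A `scov_network`: list with `r_matrix`, binary `adjacency`,
#'   achieved `density`, `requested_density` and `region_names`.
#' @export
threshold_by_density <- function(r, density, rank_by = c("signed", "abs")) {
  rank_by <- match.arg(rank_by)
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  n <- nrow(r)
  m <- n * (n - 1) / 2
  if (density <= 0 || density > 1) {
    stop("`density` must be in (0, 1]", call. = FALSE)
  }
  K <- round(density * m)
  if (K < 1) {
    stop(sprintf(
      "density %.4f keeps no edges (K = 0) for %d nodes; increase it",
      density, n), call. = FALSE)
  }
  ut <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[upper.tri(r)]
  key <- if (rank_by == "signed") vals else abs(vals)
  ord <- order(-key, -abs(vals), ut[, 1], ut[, 2])
  keep <- ord[seq_len(K)]
  A <- matrix(0, n, n)
  A[ut[keep, , drop = FALSE]] <- 1
  A <- A + t(A)
  dimnames(A) <- dimnames(r)
  rr <- r
  diag(rr) <- 0
  structure(
    list(r_matrix = rr, adjacency = A, density = K / m,
         requested_density = density, rank_by = rank_by,
         region_names = colnames(r)),
    class = "scov_network"
  )
}

#' @export
print.scov_network <- function(x, ...) {
  cat(sprintf("<scov_network> %d nodes, %d edges (density %.3f)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$density))
  invisible(x)
}

#' Check a density grid against two groups' correlation matrices
#'
#' Reports, per group, the smallest grid density at which the thresholded
#' network is fully connected, and flags a grid whose start lies below it
#' (group networks should be connected across the analysis range) or whose
#' stop reaches 0.5 or beyond (densities at or above 50% are considered
#' non-biological for binary structural networks).
#'
#' @param r_a,r_b correlation matrices of the two groups.
#' @param grid a [density_grid()].
#' @param rank_by edge ranking mode, as in [threshold_by_density()].
#' @return A list with a per-group data frame `min_connected` and logical
#'   flags `start_below_connected`, `stop_at_or_above_half`.
#' @export
validate_density_grid <- function(r_a, r_b, grid = density_grid(),
                                  rank_by = "signed") {
  min_conn <- function(r) {
    for (d in grid) {
      net <- threshold_by_density(r, d, rank_by)
      if (adjacency_connected(net$adjacency)) return(d)
    }
    NA_real_
  }
  tab <- data.frame(group = c("a", "b"),
                    min_connected_density = c(min_conn(r_a), min_conn(r_b)))
  start_flag <- any(is.na(tab$min_connected_density)) ||
    any(grid[1] < tab$min_connected_density)
  stop_flag <- max(grid) >= 0.5
  if (start_flag) {
    warning("grid start is below the smallest density at which both group ",
            "networks are connected", call. = FALSE)
  }
  if (stop_flag) {
    warning("grid reaches density >= 0.5; binary structural networks this ",
            "dense are considered non-biological", call. = FALSE)
  }
  list(min_connected = tab,
       start_below_connected = start_flag,
       stop_at_or_above_half = stop_flag)
}
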