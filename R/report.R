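# Result serialization: tidy CSV tables plus a YAML run-metadata file.
# Output is fully determined by the inputs and seeds (no timestamps), so
# re-running an identical configuration reproduces every file byte for
# byte.

#' Write a comparison report to disk
#'
#' Writes the tables produced by [compare_networks()] as tidy CSVs
#' (`global_per_density.csv`, `auc.csv`, and when present
#' `nodal_betweenness.csv` and `resilience.csv`) together with
#' `run_metadata.yaml` recording the configuration, every seed, and the
#' package version.
#'
#' @param results the list returned by [compare_networks()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(results$per_density)) {
    emit(do.call(rbind, results$per_density$tables), "global_per_density.csv")
  }
  if (!is.null(results$auc)) {
    emit(as.data.frame(results$auc), "auc.csv")
  }
  if (!is.null(results$nodal)) {
    emit(as.data.frame(results$nodal), "nodal_betweenness.csv")
  }
  if (!is.null(results$resilience)) {
    res <- as.data.frame(results$resilience)
    res$ref_density <- attr(results$resilience, "ref_density")
    res$strategy <- attr(results$resilience, "strategy")
    emit(res, "resilience.csv")
  }
  cfg <- results$config
  meta <- list(
    package = "scovnet",
    version = as.character(utils::packageVersion("scovnet")),
    config = list(
      n_perm = cfg$n_perm, alpha = cfg$alpha,
      densities = as.numeric(cfg$grid),
      n_nulls = cfg$n_nulls, n_orders = cfg$n_orders,
      rank_by = cfg$rank_by, swaps_per_edge = cfg$swaps_per_edge
    ),
    seeds = list(master = cfg$seed)
  )
  if (!is.null(results$resilience)) {
    meta$resilience <- list(
      ref_density = attr(results$resilience, "ref_density"),
      strategy = attr(results$resilience, "strategy"))
  }
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  written <- c(written, meta_path)
  invisible(written)
}

#' Plot a per-density permutation comparison
#'
#' Difference-vs-density curve for one metric with the permutation null
#' band and significance markers, in the style conventional for
#' covariance-network studies.
#'
#' @param x a `scov_perm` from [compare_global_metrics()].
#' @param metric which metric to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scov_perm <- function(x, metric = names(x$tables)[1], ...) {
  tab <- x$tables[[metric]]
  ylim <- range(tab$observed_diff, tab$null_lo, tab$null_hi)
  graphics::plot(tab$density, tab$observed_diff, type = "b", pch = 16,
                 xlab = "network density",
                 ylab = sprintf("group difference in %s", metric),
                 ylim = ylim, ...)
  graphics::arrows(tab$density, tab$null_lo, tab$density, tab$null_hi,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  graphics::points(tab$density, tab$null_mean, pch = 1, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  sig <- tab$significant
  if (any(sig)) {
    graphics::points(tab$density[sig], tab$observed_diff[sig], pch = 8,
                     col = "red")
  }
  invisible(x)
}

#' Plot a resilience comparison
#'
#' The two group curves with stars where the permutation test flags the
#' difference.
#'
#' @param x a `scov_resilience_perm` from [compare_resilience()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.scov_resilience_perm <- function(x, ...) {
  graphics::plot(x$n_removed, x$rel_gcc_a, type = "l", col = "blue",
                 xlab = "nodes removed",
                 ylab = "relative giant component size", ylim = c(0, 1),
                 ...)
  graphics::lines(x$n_removed, x$rel_gcc_b, col = "darkorange")
  sig <- x$significant
  if (any(sig)) {
    graphics::points(x$n_removed[sig],
                     pmax(x$rel_gcc_a, x$rel_gcc_b)[sig] + 0.02,
                     pch = 8, col = "red")
  }
  graphics::legend("topright", legend = c("group A", "group B"),
                   col = c("blue", "darkorange"), lty = 1, bty = "n")
  invisible(x)
}
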