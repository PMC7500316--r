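# Permutation-based group comparison of covariance-network properties.
# The observed pipeline and every permuted pipeline share the same code
# path (residualize within group -> correlate -> threshold -> metrics):
# permutation 0 is the identity relabeling and reproduces the observed
# statistics exactly.

#' Configuration for permutation comparisons
#'
#' @param n_perm number of label permutations (default 1000, as is
#'   conventional for this design).
#' @param alpha type-I error probability for the one-tailed criterion
#'   (default 0.05; the critical value is the `1 - alpha` percentile of
#'   the permutation distribution on the side of the observed difference).
#' @param grid a [density_grid()].
#' @param n_nulls null-ensemble size for small-world normalization inside
#'   each (observed or permuted) network; 20 by default. Reducing it
#'   trades sigma precision for speed.
#' @param n_orders random removal orders for resilience curves.
#' @param seed master seed; every source of randomness downstream derives
#'   from it.
#' @param rank_by edge ranking for thresholding ("signed" or "abs").
#' @param tail how the one-tailed criterion handles the data-chosen
#'   direction. `"two_sided"` (default) allocates `alpha/2` to each tail
#'   (critical value at the `1 - alpha/2` percentile on the observed side,
#'   p-value doubled), so the overall type-I rate is `alpha` even though
#'   the tested direction is read off the data. `"directional"` uses the
#'   `1 - alpha` percentile on the observed side and the raw one-sided
#'   p-value -- the convention of the graph-analysis toolboxes this
#'   package mirrors -- whose overall size is `2 * alpha` when the
#'   direction is not fixed a priori.
#' @param swaps_per_edge Maslov-Sneppen swap attempts per edge.
#' @return A `scov_config` list.
#' @export
perm_config <- function(n_perm = 1000, alpha = 0.05, grid = density_grid(),
                        n_nulls = 20, n_orders = 100, seed = 1L,
                        rank_by = c("signed", "abs"),
                        tail = c("two_sided", "directional"),
                        swaps_per_edge = 10) {
  rank_by <- match.arg(rank_by)
  tail <- match.arg(tail)
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1, inherits(grid, "scov_grid"),
            n_nulls >= 1, n_orders >= 1)
  structure(
    list(n_perm = as.integer(n_perm), alpha = alpha, grid = grid,
         n_nulls = as.integer(n_nulls), n_orders = as.integer(n_orders),
         seed = as.integer(seed), rank_by = rank_by, tail = tail,
         swaps_per_edge = swaps_per_edge),
    class = "scov_config"
  )
}

#' Permute group labels
#'
#' Pools the subjects of both cohorts and reassigns them without
#' replacement to pseudo-groups of the original sizes; covariates travel
#' with their subjects, and nuisance regression is re-fitted within each
#' pseudo-group downstream. `i = 0` is the identity relabeling (the
#' observed split). Reproducible from `(seed, i)`.
#'
#' @param cohort_a,cohort_b cohorts sharing regions and covariate schema.
#' @param seed master seed.
#' @param i permutation index (>= 1; 0 for identity).
#' @return A list of two `morph_cohort`s.
#' @export
permute_groups <- function(cohort_a, cohort_b, seed, i) {
  stopifnot(inherits(cohort_a, "morph_cohort"),
            inherits(cohort_b, "morph_cohort"))
  if (!identical(cohort_a$region_names, cohort_b$region_names)) {
    stop("cohorts must share region names", call. = FALSE)
  }
  if (i == 0) return(list(a = cohort_a, b = cohort_b))
  n_a <- nrow(cohort_a$values)
  n_b <- nrow(cohort_b$values)
  values <- rbind(cohort_a$values, cohort_b$values)
  cov <- rbind(cohort_a$covariates, cohort_b$covariates)
  rownames(values) <- make.unique(rownames(values))
  cov$subject <- rownames(values)
  idx <- with_seed(derive_seed(seed, i), sample.int(n_a + n_b))
  ia <- idx[seq_len(n_a)]
  ib <- idx[n_a + seq_len(n_b)]
  list(
    a = new_morph_cohort(values[ia, , drop = FALSE],
                         cov[ia, , drop = FALSE],
                         cohort_a$group_label, cohort_a$region_names),
    b = new_morph_cohort(values[ib, , drop = FALSE],
                         cov[ib, , drop = FALSE],
                         cohort_b$group_label, cohort_b$region_names)
  )
}

# Metrics of one thresholded network, restricted to what is requested.
#' @noRd
network_metric_values <- function(A, metrics, n_nulls, null_seed,
                                  swaps_per_edge) {
  out <- stats::setNames(numeric(length(metrics)), metrics)
  need_dist <- any(c("lp", "e_glob") %in% metrics) || "sigma" %in% metrics
  if ("cp" %in% metrics || "sigma" %in% metrics) {
    cp <- clustering_coefficient(A)
    if ("cp" %in% metrics) out["cp"] <- cp
  }
  if (need_dist) {
    D <- bfs_distances(A)
    d <- D[upper.tri(D)]
    fin <- is.finite(d)
    lp <- mean(d[fin])
    if ("lp" %in% metrics) out["lp"] <- lp
    if ("e_glob" %in% metrics) {
      inv <- 1 / d
      inv[!fin] <- 0
      out["e_glob"] <- mean(inv)
    }
  }
  if ("e_loc" %in% metrics) out["e_loc"] <- local_efficiency(A)
  if ("sigma" %in% metrics) {
    ens <- make_null_ensemble(A, n_nulls = n_nulls, seed = null_seed,
                              swaps_per_edge = swaps_per_edge)
    gamma <- cp / ens$cp_rand
    lambda <- lp / ens$lp_rand
    out["sigma"] <- gamma / lambda
  }
  out
}

# Metric-vs-density curves for one cohort: the full construction pipeline.
#' @noRd
cohort_curves <- function(cohort, config, metrics, include_nodal = FALSE,
                          null_seed = config$seed) {
  res <- residualize(cohort)
  r <- correlation_matrix(res)
  grid <- config$grid
  nd <- length(grid)
  global <- matrix(NA_real_, nd, length(metrics),
                   dimnames = list(NULL, metrics))
  nodal <- if (include_nodal) {
    matrix(NA_real_, nd, ncol(r), dimnames = list(NULL, colnames(r)))
  }
  for (k in seq_len(nd)) {
    net <- tryCatch(
      threshold_by_density(r, grid[k], config$rank_by),
      error = function(e) {
        stop("thresholding failed at density ", grid[k],
             " (", conditionMessage(e), "); use a higher grid start",
             call. = FALSE)
      })
    A <- net$adjacency
    if (sum(A) == 0) {
      stop("network has zero edges at density ", grid[k],
           "; use a higher grid start", call. = FALSE)
    }
    if (length(metrics) > 0) {
      global[k, ] <- network_metric_values(
        A, metrics, config$n_nulls, derive_seed(null_seed, k),
        config$swaps_per_edge)
    }
    if (include_nodal) {
      nodal[k, ] <- suppressWarnings(nodal_betweenness(A)$norm)
    }
  }
  list(global = global, nodal = nodal, r_matrix = r)
}

# Permutation summary for a single evaluation point: critical value at the
# tail-level percentile on the side of the observed difference, p-value
# with the (b + 1)/(n + 1) correction (doubled and capped at 1 under the
# default two-sided convention).
#' @noRd
perm_point_test <- function(obs, perm, alpha, tail = "two_sided") {
  if (obs == 0) {
    # no observed direction: every permutation is at least as extreme
    return(c(null_mean = mean(perm),
             null_lo = stats::quantile(perm, 0.025, names = FALSE),
             null_hi = stats::quantile(perm, 0.975, names = FALSE),
             critical_value = stats::quantile(perm, 1 - alpha,
                                              names = FALSE),
             p_value = 1, significant = 0))
  }
  side_alpha <- if (tail == "two_sided") alpha / 2 else alpha
  if (obs >= 0) {
    crit <- stats::quantile(perm, 1 - side_alpha, names = FALSE)
    b <- sum(perm >= obs)
    sig <- obs > crit
  } else {
    crit <- stats::quantile(perm, side_alpha, names = FALSE)
    b <- sum(perm <= obs)
    sig <- obs < crit
  }
  p1 <- (b + 1) / (length(perm) + 1)
  p <- if (tail == "two_sided") min(1, 2 * p1) else p1
  c(null_mean = mean(perm),
    null_lo = stats::quantile(perm, 0.025, names = FALSE),
    null_hi = stats::quantile(perm, 0.975, names = FALSE),
    critical_value = crit,
    p_value = p,
    significant = as.numeric(sig))
}

#' @noRd
auc_trapz <- function(x, y) {
  if (length(x) < 2) return(y[1] * 0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Core permutation engine: observed and permuted metric-vs-density curves
# (group A minus group B), optionally with nodal betweenness curves.
#' @noRd
run_permutations <- function(cohort_a, cohort_b, config, metrics,
                             include_nodal = FALSE) {
  grid <- config$grid
  nd <- length(grid)
  nm <- length(metrics)
  n_regions <- length(cohort_a$region_names)
  one_pair <- function(pair, i) {
    ca <- cohort_curves(pair$a, config, metrics, include_nodal,
                        null_seed = derive_seed(config$seed, 2 * i))
    cb <- cohort_curves(pair$b, config, metrics, include_nodal,
                        null_seed = derive_seed(config$seed, 2 * i + 1))
    list(a = ca, b = cb)
  }
  obs <- one_pair(permute_groups(cohort_a, cohort_b, config$seed, 0), 0)
  perm_global <- array(NA_real_, c(config$n_perm, nd, nm))
  perm_nodal <- if (include_nodal) {
    array(NA_real_, c(config$n_perm, nd, n_regions))
  }
  for (i in seq_len(config$n_perm)) {
    pr <- one_pair(permute_groups(cohort_a, cohort_b, config$seed, i), i)
    if (nm > 0) perm_global[i, , ] <- pr$a$global - pr$b$global
    if (include_nodal) perm_nodal[i, , ] <- pr$a$nodal - pr$b$nodal
  }
  list(grid = grid, metrics = metrics, obs = obs,
       perm_global = perm_global, perm_nodal = perm_nodal)
}

#' Per-density permutation comparison of global network metrics
#'
#' Runs the full construction pipeline on the observed groups and on
#' `n_perm` random relabelings, and compares the observed group difference
#' (A minus B) of each metric at each density against its permutation
#' distribution: one-tailed in the direction of the observed difference,
#' critical value at the `1 - alpha` percentile, permutation p-value with
#' the `(b + 1)/(n_perm + 1)` correction.
#'
#' @param cohort_a,cohort_b the two groups.
#' @param config a [perm_config()].
#' @param metrics which metrics to compare; any of `"cp"`, `"lp"`,
#'   `"e_glob"`, `"e_loc"`, `"sigma"`. `sigma` builds a fresh null
#'   ensemble inside every permuted network and dominates the cost.
#' @param p_adjust `"none"` (default, mirroring common practice for these
#'   per-density tests) or `"BH"` to append a Benjamini-Hochberg adjusted
#'   p-value across the densities of each metric.
#' @return A `scov_perm` object: per metric, a data frame with columns
#'   `density`, `observed_diff`, `null_mean`, `null_lo`, `null_hi`,
#'   `critical_value`, `p_value`, `significant` (and `p_adjusted` when
#'   requested).
#' @export
compare_global_metrics <- function(cohort_a, cohort_b,
                                   config = perm_config(),
                                   metrics = c("cp", "lp", "e_glob",
                                               "e_loc", "sigma"),
                                   p_adjust = c("none", "BH")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  p_adjust <- match.arg(p_adjust)
  run <- run_permutations(cohort_a, cohort_b, config, metrics)
  summarize_per_density(run, config, p_adjust)
}

#' @noRd
summarize_per_density <- function(run, config, p_adjust = "none") {
  metrics <- run$metrics
  out <- lapply(seq_along(metrics), function(j) {
    obs_diff <- run$obs$a$global[, j] - run$obs$b$global[, j]
    stats_tab <- t(vapply(seq_along(run$grid), function(k) {
      perm_point_test(obs_diff[k], run$perm_global[, k, j], config$alpha, config$tail)
    }, numeric(6)))
    df <- data.frame(density = as.numeric(run$grid),
                     metric = metrics[j],
                     observed_a = run$obs$a$global[, j],
                     observed_b = run$obs$b$global[, j],
                     observed_diff = obs_diff)
    df <- cbind(df, as.data.frame(stats_tab))
    df$significant <- df$significant > 0
    if (p_adjust == "BH") {
      df$p_adjusted <- stats::p.adjust(df$p_value, method = "BH")
    }
    df
  })
  names(out) <- metrics
  structure(list(tables = out, config = config), class = "scov_perm")
}

#' @export
print.scov_perm <- function(x, ...) {
  for (m in names(x$tables)) {
    tab <- x$tables[[m]]
    cat(sprintf("%s: %d/%d densities significant (alpha = %.2f)\n",
                m, sum(tab$significant), nrow(tab), x$config$alpha))
  }
  invisible(x)
}

#' AUC permutation comparison of global network metrics
#'
#' Summarizes each metric-vs-density curve by its trapezoidal area under
#' the curve over the density grid and compares the observed AUC
#' difference between groups to its permutation distribution, reducing the
#' sensitivity of the comparison to any single threshold.
#'
#' @inheritParams compare_global_metrics
#' @return A `scov_auc` data frame: one row per metric with `auc_a`,
#'   `auc_b`, `diff`, permutation summaries, `p_value` and `significant`.
#' @export
compare_auc <- function(cohort_a, cohort_b, config = perm_config(),
                        metrics = c("cp", "lp", "e_glob", "e_loc",
                                    "sigma")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  run <- run_permutations(cohort_a, cohort_b, config, metrics)
  summarize_auc(run, config)
}

#' @noRd
summarize_auc <- function(run, config) {
  metrics <- run$metrics
  x <- as.numeric(run$grid)
  rows <- lapply(seq_along(metrics), function(j) {
    auc_a <- auc_trapz(x, run$obs$a$global[, j])
    auc_b <- auc_trapz(x, run$obs$b$global[, j])
    perm_auc <- vapply(seq_len(config$n_perm), function(i) {
      auc_trapz(x, run$perm_global[i, , j])
    }, numeric(1))
    st <- perm_point_test(auc_a - auc_b, perm_auc, config$alpha, config$tail)
    data.frame(metric = metrics[j], auc_a = auc_a, auc_b = auc_b,
               diff = auc_a - auc_b, t(st))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$significant > 0
  attr(out, "config") <- config
  class(out) <- c("scov_auc", "data.frame")
  out
}

#' Regional permutation comparison of normalized nodal betweenness
#'
#' For every region, the normalized-betweenness curve across the density
#' grid is summarized by its trapezoidal AUC and the group difference is
#' tested by the same one-tailed permutation scheme. The output mirrors
#' the conventional regional table: region, per-group betweenness AUC,
#' difference and p-value.
#'
#' @inheritParams compare_global_metrics
#' @return A `scov_nodal_perm` data frame with one row per region (with a
#'   `p_adjusted` column across regions when `p_adjust = "BH"`).
#' @export
compare_nodal_betweenness <- function(cohort_a, cohort_b,
                                      config = perm_config(),
                                      p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  run <- run_permutations(cohort_a, cohort_b, config, character(0),
                          include_nodal = TRUE)
  summarize_nodal(run, config, cohort_a$region_names, p_adjust)
}

#' @noRd
summarize_nodal <- function(run, config, regions, p_adjust = "none") {
  x <- as.numeric(run$grid)
  rows <- lapply(seq_along(regions), function(j) {
    auc_a <- auc_trapz(x, run$obs$a$nodal[, j])
    auc_b <- auc_trapz(x, run$obs$b$nodal[, j])
    perm_auc <- vapply(seq_len(config$n_perm), function(i) {
      auc_trapz(x, run$perm_nodal[i, , j])
    }, numeric(1))
    st <- perm_point_test(auc_a - auc_b, perm_auc, config$alpha, config$tail)
    data.frame(region = regions[j], betweenness_a = auc_a,
               betweenness_b = auc_b, diff = auc_a - auc_b, t(st))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$significant > 0
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  attr(out, "config") <- config
  class(out) <- c("scov_nodal_perm", "data.frame")
  out
}

#' Permutation comparison of resilience curves
#'
#' Builds each group's network at a single reference density (by default
#' the smallest grid density at which both observed group networks are
#' connected), computes the relative giant-component curve under the
#' chosen removal strategy, and compares the per-`n_removed` group
#' difference to its permutation distribution.
#'
#' @inheritParams compare_global_metrics
#' @param strategy `"targeted_betweenness"`, `"random_failure"` or
#'   `"targeted_degree"`.
#' @param ref_density reference density; `NULL` picks the default above.
#' @return A `scov_resilience_perm` data frame: per `n_removed`, the two
#'   group curves, difference, permutation summaries and significance;
#'   the reference density is stored in the `ref_density` attribute.
#' @export
compare_resilience <- function(cohort_a, cohort_b, config = perm_config(),
                               strategy = c("targeted_betweenness",
                                            "random_failure",
                                            "targeted_degree"),
                               ref_density = NULL) {
  strategy <- match.arg(strategy)
  r_a <- correlation_matrix(residualize(cohort_a))
  r_b <- correlation_matrix(residualize(cohort_b))
  if (is.null(ref_density)) {
    conn <- vapply(config$grid, function(d) {
      adjacency_connected(threshold_by_density(r_a, d,
                                               config$rank_by)$adjacency) &&
        adjacency_connected(threshold_by_density(r_b, d,
                                                 config$rank_by)$adjacency)
    }, logical(1))
    if (!any(conn)) {
      stop("no grid density leaves both observed networks connected; ",
           "supply `ref_density` explicitly", call. = FALSE)
    }
    ref_density <- as.numeric(config$grid[which(conn)[1]])
  }
  curve_for <- function(cohort, seed_offset) {
    r <- correlation_matrix(residualize(cohort))
    A <- threshold_by_density(r, ref_density, config$rank_by)$adjacency
    switch(strategy,
           random_failure = random_failure_curve(
             A, n_orders = config$n_orders,
             seed = derive_seed(config$seed, seed_offset))$rel_gcc,
           targeted_betweenness = targeted_attack_curve(
             A, "betweenness")$rel_gcc,
           targeted_degree = targeted_attack_curve(A, "degree")$rel_gcc)
  }
  obs_a <- curve_for(cohort_a, 0)
  obs_b <- curve_for(cohort_b, 1)
  n <- length(obs_a) - 1
  perm <- matrix(NA_real_, config$n_perm, n + 1)
  for (i in seq_len(config$n_perm)) {
    pr <- permute_groups(cohort_a, cohort_b, config$seed, i)
    perm[i, ] <- curve_for(pr$a, 2 * i) - curve_for(pr$b, 2 * i + 1)
  }
  obs_diff <- obs_a - obs_b
  st <- t(vapply(seq_len(n + 1), function(k) {
    perm_point_test(obs_diff[k], perm[, k], config$alpha, config$tail)
  }, numeric(6)))
  out <- data.frame(n_removed = 0:n, rel_gcc_a = obs_a, rel_gcc_b = obs_b,
                    observed_diff = obs_diff, as.data.frame(st))
  out$significant <- out$significant > 0
  # endpoints are equal by construction; never flag them
  out$significant[c(1, n + 1)] <- FALSE
  attr(out, "ref_density") <- ref_density
  attr(out, "strategy") <- strategy
  attr(out, "config") <- config
  class(out) <- c("scov_resilience_perm", "data.frame")
  out
}

#' Full two-group comparison in one call
#'
#' Convenience umbrella for the complete analysis: per-density and AUC
#' permutation comparisons of the global metrics, optionally the regional
#' betweenness table and a resilience comparison. This is what the
#' command-line `compare` entry point and [write_report()] consume.
#'
#' @inheritParams compare_global_metrics
#' @param nodal include the regional betweenness comparison.
#' @param resilience_strategy `NULL` to skip, otherwise passed to
#'   [compare_resilience()].
#' @param ref_density reference density for the resilience comparison
#'   (`NULL` for the connectivity-based default).
#' @return A list with elements `per_density`, `auc`, and optionally
#'   `nodal` and `resilience`, plus the `config`.
#' @export
compare_networks <- function(cohort_a, cohort_b, config = perm_config(),
                             metrics = c("cp", "lp", "e_glob", "e_loc",
                                         "sigma"),
                             nodal = TRUE,
                             resilience_strategy = "targeted_betweenness",
                             ref_density = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  run <- run_permutations(cohort_a, cohort_b, config, metrics,
                          include_nodal = nodal)
  out <- list(
    per_density = summarize_per_density(run, config),
    auc = summarize_auc(run, config)
  )
  if (nodal) {
    out$nodal <- summarize_nodal(run, config, cohort_a$region_names)
  }
  if (!is.null(resilience_strategy)) {
    out$resilience <- compare_resilience(cohort_a, cohort_b, config,
                                         resilience_strategy,
                                         ref_density = ref_density)
  }
  out$config <- config
  out
}
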