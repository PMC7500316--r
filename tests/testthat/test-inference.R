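test_that("permuted groups keep sizes, pool membership and reproducibility", {
  pair <- small_null_pair(seed = 3)
  p1 <- permute_groups(pair$A, pair$B, seed = 11, i = 1)
  expect_equal(nrow(p1$a$values), nrow(pair$A$values))
  expect_equal(nrow(p1$b$values), nrow(pair$B$values))
  pool <- rbind(pair$A$values, pair$B$values)
  got <- rbind(p1$a$values, p1$b$values)
  expect_equal(dim(got), dim(pool))
  # every pooled subject appears exactly once (match rows by value)
  key <- function(m) sort(apply(m, 1, function(x) paste(signif(x, 12),
                                                        collapse = ",")))
  expect_identical(key(got), key(pool))
  # covariates travel with their subjects
  all_cov <- rbind(pair$A$covariates, pair$B$covariates)
  m <- match(rownames(p1$a$values), make.unique(rownames(pool)))
  expect_equal(p1$a$covariates$age, all_cov$age[m])
  # reproducible from (seed, i); different i differs
  p1b <- permute_groups(pair$A, pair$B, seed = 11, i = 1)
  expect_identical(p1$a$values, p1b$a$values)
  p2 <- permute_groups(pair$A, pair$B, seed = 11, i = 2)
  expect_false(identical(p1$a$values, p2$a$values))
  # i = 0 is the identity relabeling
  p0 <- permute_groups(pair$A, pair$B, seed = 11, i = 0)
  expect_identical(p0$a$values, pair$A$values)
})

test_that("each subject lands in pseudo-group A at its exchangeable frequency", {
  pair <- small_null_pair(seed = 5, n_regions = 8, n = 10)
  n_a <- 10
  count_first <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    p <- permute_groups(pair$A, pair$B, seed = 2, i = i)
    if (rownames(pair$A$values)[1] %in% rownames(p$a$values)) {
      count_first <- count_first + 1
    }
  }
  expect_lt(abs(count_first / n_rep - 0.5), 0.08)
})

test_that("a cohort compared with itself yields zero differences and no rejections", {
  pair <- small_null_pair(seed = 9, n_regions = 12, n = 15)
  cfg <- perm_config(n_perm = 30, grid = density_grid(0.2, 0.4, 0.1),
                     n_nulls = 3, seed = 7)
  res <- compare_global_metrics(pair$A, pair$A, cfg,
                                metrics = c("cp", "e_glob"))
  for (tab in res$tables) {
    expect_equal(tab$observed_diff, rep(0, nrow(tab)), tolerance = 1e-12)
    expect_false(any(tab$significant))
    expect_true(all(tab$p_value >= 0.9))
  }
  auc <- compare_auc(pair$A, pair$A, cfg, metrics = "cp")
  expect_equal(auc$diff, 0, tolerance = 1e-12)
  expect_gt(auc$p_value, 0.9)
  nod <- compare_nodal_betweenness(pair$A, pair$A,
                                   perm_config(n_perm = 10,
                                               grid = density_grid(0.2, 0.4,
                                                                   0.1),
                                               seed = 3))
  expect_equal(nod$diff, rep(0, 12), tolerance = 1e-12)
})

test_that("identity permutation reproduces the observed statistics through the same path", {
  pair <- small_null_pair(seed = 13, n_regions = 12, n = 15)
  cfg <- perm_config(n_perm = 5, grid = density_grid(0.2, 0.4, 0.1),
                     n_nulls = 3, seed = 19)
  p0 <- permute_groups(pair$A, pair$B, cfg$seed, 0)
  obs_direct <- scovnet:::cohort_curves(
    p0$a, cfg, c("cp", "lp"),
    null_seed = scovnet:::derive_seed(cfg$seed, 0))
  res <- compare_global_metrics(pair$A, pair$B, cfg, metrics = c("cp", "lp"))
  expect_equal(res$tables$cp$observed_a, unname(obs_direct$global[, "cp"]),
               tolerance = 1e-12)
  expect_equal(res$tables$lp$observed_a, unname(obs_direct$global[, "lp"]),
               tolerance = 1e-12)
})

test_that("AUC equals the hand trapezoid and is linear in the curve", {
  x <- c(0.1, 0.2, 0.4)
  y <- c(2, 3, 1)
  expect_equal(scovnet:::auc_trapz(x, y),
               0.1 * (2 + 3) / 2 + 0.2 * (3 + 1) / 2, tolerance = 1e-14)
  # constant curve: c * width
  expect_equal(scovnet:::auc_trapz(x, rep(4, 3)), 4 * 0.3, tolerance = 1e-14)
  # AUC of a difference = difference of AUCs
  y2 <- c(0.5, 1.5, 2.5)
  expect_equal(scovnet:::auc_trapz(x, y - y2),
               scovnet:::auc_trapz(x, y) - scovnet:::auc_trapz(x, y2),
               tolerance = 1e-14)
})

test_that("p-values respect their permutation bounds and significance matches the criterion", {
  pair <- small_null_pair(seed = 23, n_regions = 12, n = 15)
  cfg <- perm_config(n_perm = 40, grid = density_grid(0.2, 0.4, 0.1),
                     n_nulls = 2, seed = 29)
  res <- compare_global_metrics(pair$A, pair$B, cfg,
                                metrics = c("cp", "lp", "e_glob"))
  for (tab in res$tables) {
    expect_true(all(tab$p_value >= 1 / (cfg$n_perm + 1)))
    expect_true(all(tab$p_value <= 1))
    # significance flag consistent with observed-direction critical value
    up <- tab$observed_diff >= 0
    expect_equal(tab$significant,
                 ifelse(up, tab$observed_diff > tab$critical_value,
                        tab$observed_diff < tab$critical_value))
  }
})

test_that("optional BH adjustment appends monotone adjusted p-values", {
  pair <- small_null_pair(seed = 31, n_regions = 10, n = 12)
  cfg <- perm_config(n_perm = 15, grid = density_grid(0.2, 0.4, 0.1),
                     seed = 33)
  res <- compare_global_metrics(pair$A, pair$B, cfg, metrics = "cp",
                                p_adjust = "BH")
  tab <- res$tables$cp
  expect_true("p_adjusted" %in% names(tab))
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
  expect_true(all(tab$p_adjusted <= 1))
  # default omits the column
  res0 <- compare_global_metrics(pair$A, pair$B, cfg, metrics = "cp")
  expect_false("p_adjusted" %in% names(res0$tables$cp))
})

test_that("a built-in clustering effect is detected with the right sign", {
  spec_a <- ground_truth_spec(n_regions = 40,
                              topology = topology_watts_strogatz(6, 0.05),
                              base_correlation = 0.6, noise_sd = 0.3,
                              seed = 37)
  spec_b <- effect_preset(spec_a, "reduced_clustering")
  pair <- generate_paired_cohorts(spec_a, spec_b, n_a = 31, n_b = 31)
  cfg <- perm_config(n_perm = 60, grid = density_grid(0.1, 0.3, 0.05),
                     seed = 41)
  res <- compare_global_metrics(pair$A, pair$B, cfg, metrics = "cp")
  tab <- res$tables$cp
  # group A (clustered generator) has larger Cp at a majority of densities
  expect_gt(mean(tab$observed_diff > 0), 0.5)
  auc <- compare_auc(pair$A, pair$B, cfg, metrics = "cp")
  expect_gt(auc$diff, 0)
})

test_that("resilience comparison: self-comparison flags nothing, endpoints are zero", {
  pair <- small_null_pair(seed = 43, n_regions = 14, n = 15)
  cfg <- perm_config(n_perm = 20, grid = density_grid(0.2, 0.4, 0.1),
                     n_orders = 10, seed = 47)
  res <- compare_resilience(pair$A, pair$A, cfg, "targeted_betweenness")
  expect_equal(res$observed_diff, rep(0, nrow(res)), tolerance = 1e-12)
  expect_false(any(res$significant))
  expect_equal(res$observed_diff[c(1, nrow(res))], c(0, 0))
  expect_true(attr(res, "ref_density") %in% as.numeric(cfg$grid))
})

test_that("a bridge-hub generator raises that region's betweenness AUC difference", {
  spec_b <- ground_truth_spec(n_regions = 24,
                              topology = topology_lattice(4),
                              base_correlation = 0.7, noise_sd = 0.2,
                              seed = 53)
  spec_a <- effect_preset(spec_b, "bridge_hub")
  pair <- generate_paired_cohorts(spec_a, spec_b, n_a = 40, n_b = 40)
  cfg <- perm_config(n_perm = 10, grid = density_grid(0.15, 0.3, 0.05),
                     seed = 59)
  nod <- compare_nodal_betweenness(pair$A, pair$B, cfg)
  expect_gt(nod$diff[1], 0) # region 1 is the sole bridge in group A
})

test_that("compare_networks is deterministic end to end (byte-identical reports)", {
  pair <- small_null_pair(seed = 61, n_regions = 12, n = 15)
  cfg <- perm_config(n_perm = 12, grid = density_grid(0.2, 0.4, 0.1),
                     n_nulls = 2, n_orders = 10, seed = 67)
  run <- function(dir) {
    res <- compare_networks(pair$A, pair$B, cfg,
                            metrics = c("cp", "e_glob"), nodal = TRUE,
                            resilience_strategy = "targeted_betweenness",
                            ref_density = 0.4)
    write_report(res, dir)
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- run(d1)
  f2 <- run(d2)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1)) {
    expect_identical(readBin(f1[k], "raw", file.size(f1[k])),
                     readBin(f2[k], "raw", file.size(f2[k])),
                     label = basename(f1[k]))
  }
})
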