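test_that("residualize matches an explicit normal-equations solve", {
  covariates <- data.frame(subject = paste0("s", 1:4),
                           age = c(45, 52, 60, 66),
                           sex = c(0, 1, 0, 1),
                           tiv = c(1400, 1520, 1380, 1465))
  values <- cbind(a = c(3.2, 4.1, 2.8, 5.0),
                  b = c(10.0, 9.1, 11.2, 8.7),
                  c = c(1.0, 2.0, 1.5, 2.5))
  rownames(values) <- covariates$subject
  cohort <- new_morph_cohort(values, covariates, "toy")
  # hand-built design: 4 subjects, but intercept + 3 covariates saturates;
  # the solve still defines unique fitted values, residuals are zero
  res <- residualize(cohort)
  X <- cbind(1, covariates$age, covariates$sex, covariates$tiv)
  beta <- solve(t(X) %*% X, t(X) %*% values)
  expect_equal(res, values - X %*% beta, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("residuals are orthogonal to covariates and mean-centered", {
  spec <- ground_truth_spec(n_regions = 10, base_correlation = 0.4,
                            covariate_effects = c(age = -0.05, sex = 0.6,
                                                  tiv = 2e-3),
                            seed = 2)
  cohort <- generate_cohort(spec, 40, "x")
  res <- residualize(cohort)
  expect_equal(colMeans(res), rep(0, 10), ignore_attr = TRUE,
               tolerance = 1e-10)
  for (v in c("age", "sex", "tiv")) {
    expect_equal(drop(crossprod(cohort$covariates[[v]], res)), rep(0, 10),
                 ignore_attr = TRUE, tolerance = 1e-7)
  }
})

test_that("residualize rejects collinear covariates by name", {
  covariates <- data.frame(subject = paste0("s", 1:6),
                           age = c(50, 50, 50, 50, 50, 50), # constant: collinear with intercept
                           sex = c(0, 1, 0, 1, 0, 1),
                           tiv = rnorm(6, 1450, 50))
  values <- matrix(rnorm(18), 6, 3, dimnames = list(covariates$subject,
                                                    c("a", "b", "c")))
  cohort <- new_morph_cohort(values, covariates, "toy")
  expect_error(residualize(cohort), "collinear.*age")
})

test_that("correlation matrix matches the explicit Pearson formula", {
  x <- cbind(a = c(1.0, 2.0, 4.0, 3.0),
             b = c(2.1, 1.9, 5.5, 2.8),
             c = c(9.0, 7.0, 3.0, 5.0))
  r <- correlation_matrix(x)
  pearson <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(r["a", "b"], pearson(x[, "a"], x[, "b"]), tolerance = 1e-12)
  expect_equal(r["a", "c"], pearson(x[, "a"], x[, "c"]), tolerance = 1e-12)
  expect_equal(r["b", "c"], pearson(x[, "b"], x[, "c"]), tolerance = 1e-12)
  expect_equal(diag(r), rep(0, 3), ignore_attr = TRUE)
  expect_equal(r, t(r))
  # duplicated and negated regions hit the +/-1 bounds
  y <- cbind(x, d = x[, "a"], e = -x[, "a"])
  r2 <- correlation_matrix(y)
  expect_equal(r2["a", "d"], 1, tolerance = 1e-12)
  expect_equal(r2["a", "e"], -1, tolerance = 1e-12)
  # degenerate inputs
  expect_error(correlation_matrix(x[1:2, ]), "at least 3")
  xc <- cbind(x, flat = c(1, 1, 1, 1))
  expect_error(correlation_matrix(xc), "zero-variance.*flat")
})

test_that("thresholding keeps the top-K pairs of a full sorting oracle", {
  set.seed(31)
  n <- 5
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- runif(10, -1, 1)
  r <- r + t(r)
  dimnames(r) <- list(letters[1:5], letters[1:5])
  net <- threshold_by_density(r, 0.4)
  # oracle: rank all pairs by signed r, take top 4
  ut <- which(upper.tri(r), arr.ind = TRUE)
  ord <- order(-r[upper.tri(r)])
  keep <- ut[ord[1:4], ]
  expected <- matrix(0, n, n)
  expected[keep] <- 1
  expected <- expected + t(expected)
  expect_equal(unname(net$adjacency), expected)
  expect_equal(net$density, 4 / 10)
  # absolute-value ranking picks the strongest magnitudes instead
  net_abs <- threshold_by_density(r, 0.4, rank_by = "abs")
  ord2 <- order(-abs(r[upper.tri(r)]))
  keep2 <- ut[ord2[1:4], ]
  expected2 <- matrix(0, n, n)
  expected2[keep2] <- 1
  expected2 <- expected2 + t(expected2)
  expect_equal(unname(net_abs$adjacency), expected2)
})

test_that("threshold limits: complete graph at density 1, single top edge at minimum", {
  set.seed(5)
  n <- 7
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- runif(n * (n - 1) / 2)
  r <- r + t(r)
  expect_equal(sum(threshold_by_density(r, 1)$adjacency), n * (n - 1))
  m <- n * (n - 1) / 2
  one <- threshold_by_density(r, 1 / m)
  expect_equal(sum(one$adjacency), 2)
  top <- which(one$adjacency == 1, arr.ind = TRUE)[1, ]
  expect_equal(r[top[1], top[2]], max(r[upper.tri(r)]))
  expect_error(threshold_by_density(r, 1e-6), "K = 0")
})

test_that("edge sets are nested along the grid and density is monotone", {
  set.seed(13)
  n <- 20
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- runif(n * (n - 1) / 2, -1, 1)
  r <- r + t(r)
  prev <- NULL
  prev_d <- 0
  for (d in density_grid(0.1, 0.5, 0.1)) {
    net <- threshold_by_density(r, d)
    expect_gte(net$density, prev_d)
    if (!is.null(prev)) {
      expect_true(all(net$adjacency[prev == 1] == 1)) # superset of edges
    }
    prev <- net$adjacency
    prev_d <- net$density
  }
})

test_that("thresholding is invariant to rank-preserving transforms; pipeline to shifts", {
  set.seed(41)
  n <- 12
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- runif(n * (n - 1) / 2, -0.9, 0.9)
  r <- r + t(r)
  # strictly monotone transform of r preserves the edge set
  r2 <- tanh(2 * r)
  expect_equal(threshold_by_density(r, 0.3)$adjacency,
               threshold_by_density(r2, 0.3)$adjacency)
  # adding a constant to one region's values does not change correlations
  spec <- ground_truth_spec(n_regions = 8, seed = 6)
  cohort <- generate_cohort(spec, 25, "x")
  shifted <- cohort
  shifted$values[, 3] <- shifted$values[, 3] + 100
  expect_equal(correlation_matrix(residualize(cohort)),
               correlation_matrix(residualize(shifted)), tolerance = 1e-10)
})

test_that("density grid validation reports minimum connected density", {
  # complete-graph correlations: connected at every density
  n <- 10
  r_full <- matrix(0.9, n, n)
  diag(r_full) <- 0
  # two blocks with no cross-correlation: disconnected until the grid
  # reaches far enough down the ranking
  r_split <- matrix(0, n, n)
  r_split[1:5, 1:5] <- 0.9
  r_split[6:10, 6:10] <- 0.9
  diag(r_split) <- 0
  suppressWarnings(rep <- validate_density_grid(r_full, r_split,
                                                density_grid(0.1, 0.4, 0.1)))
  expect_equal(rep$min_connected$min_connected_density[1], 0.2)
  expect_true(is.na(rep$min_connected$min_connected_density[2]) ||
                rep$min_connected$min_connected_density[2] > 0.2)
  expect_true(rep$start_below_connected)
  expect_false(rep$stop_at_or_above_half)
  expect_warning(validate_density_grid(r_full, r_full,
                                       density_grid(0.2, 0.5, 0.1)),
                 "0.5")
})

test_that("invalid grids are rejected", {
  expect_error(density_grid(0, 0.5, 0.02))
  expect_error(density_grid(0.5, 0.1, 0.02))
  expect_error(density_grid(0.1, 1.0, 0.02))
})
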