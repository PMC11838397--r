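line5 <- function() {
  co <- spatial_coordinates(cbind(0:4, rep(0, 5)), is_rescaled = TRUE)
  idx <- build_spatial_index(co, "exact")
  list(co = co,
       p1 = compute_patch_matrix(idx, 1.5),
       p2 = compute_patch_matrix(idx, 3.5))
}

test_that("variance ratio matches the hand-evaluated 5-spot line", {
  # spots at x = 0..4, feature [0,0,1,0,0], R1 = 1.5, R2 = 3.5.
  # Small patches: {2},{1,3},{2,4},{3,5},{4} -> means (0, .5, 0, .5, 0).
  # Big patches: {2,3,4},{1,3,4,5},{1,2,4,5},{1,2,3,5},{2,3,4}
  #   -> means (1/3, 1/4, 0, 1/4, 1/3).
  env <- line5()
  X <- matrix(c(0, 0, 1, 0, 0), 1, 5)
  raw <- expression_matrix(X, "f")
  scl <- scale_expression_maxabs(raw)$expr
  vr <- compute_variance_ratio(raw, scl, env$p1, env$p2)
  m1 <- c(0, .5, 0, .5, 0)
  m2 <- c(1/3, 1/4, 0, 1/4, 1/3)
  v1 <- mean((m1 - mean(m1))^2)
  v2 <- mean((m2 - mean(m2))^2)
  expect_equal(vr$weight, 1)        # single feature: max-variance by default
  expect_equal(vr$ratio, v2 / v1, tolerance = 1e-12)
  expect_false(vr$excluded)
})

test_that("identical features get identical statistic triples", {
  env <- line5()
  X <- rbind(c(0, 0, 1, 0, 0), c(0, 0, 1, 0, 0), c(5, 1, 2, 0, 3))
  raw <- expression_matrix(X)
  scl <- scale_expression_maxabs(raw)$expr
  vr <- compute_variance_ratio(raw, scl, env$p1, env$p2)
  expect_equal(vr[1, -1], vr[2, -1], ignore_attr = TRUE)
  # weight hits 1 exactly for the max-raw-variance feature
  expect_equal(max(vr$weight), 1)
  expect_equal(which.max(vr$weight), 3L)
})

test_that("mismatched raw/scaled feature sets are rejected", {
  env <- line5()
  raw <- expression_matrix(matrix(1:10, 2, 5))
  scl <- scale_expression_maxabs(
    expression_matrix(matrix(1:15, 3, 5)))$expr
  expect_error(compute_variance_ratio(raw, scl, env$p1, env$p2),
               "different feature sets")
})

test_that("lognormal fit is Gaussian MLE on the log ratios", {
  expect_error(fit_lognormal_null(rep(2, 50)), "degenerate")
  expect_error(fit_lognormal_null(c(1, 2, 3)), "need >= 10")

  fit <- fit_lognormal_null(rep(exp(0:2), 4))
  expect_equal(fit$mu, 1)
  expect_equal(fit$s, sqrt(mean((rep(0:2, 4) - 1)^2)))

  # large-sample recovery: MLE within 3 standard errors
  set.seed(21)
  n <- 10000
  draws <- exp(rnorm(n, 0.3, 0.7))
  fit <- fit_lognormal_null(draws)
  expect_lt(abs(fit$mu - 0.3), 3 * 0.7 / sqrt(n))
  expect_lt(abs(fit$s - 0.7), 3 * 0.7 / sqrt(2 * n))
  # non-positive ratios are ignored by the fit
  fit2 <- fit_lognormal_null(c(draws, 0, -1, NaN))
  expect_equal(fit2$mu, fit$mu)
})

test_that("p-values hit the closed-form quantiles of the fitted null", {
  set.seed(2)
  fit <- fit_lognormal_null(exp(rnorm(500, 0.4, 1.1)))
  expect_equal(compute_pvalues(exp(fit$mu), fit), 0.5)
  expect_equal(compute_pvalues(exp(fit$mu + 1.6449 * fit$s), fit), 0.05,
               tolerance = 1e-4)
  # permutation null: add-one empirical tail
  pn <- structure(list(kind = "permutation", ratios = c(1, 2, 3, 4)),
                  class = "null_model")
  expect_equal(compute_pvalues(5, pn), 1 / 5)
  expect_equal(compute_pvalues(3, pn), 3 / 5)
  # non-positive ratios -> p = 1 under either null
  expect_equal(compute_pvalues(c(0, -2), fit), c(1, 1))
  # monotone: p non-increasing in the ratio
  r <- sort(exp(rnorm(50, 0, 2)))
  expect_true(all(diff(compute_pvalues(r, fit)) <= 0))
  expect_true(all(diff(compute_pvalues(r, structure(
    list(kind = "permutation", ratios = exp(rnorm(200))),
    class = "null_model"))) <= 0))
})

test_that("permutation null is seeded, validated, and tracks the lognormal", {
  sim <- simulate_2d("hotspot", n_svf = 30, n_null = 270, fc = 4,
                     tau2 = 0.2, seed = 5)
  co <- rescale_coordinates(sim$coords)$coords
  idx <- build_spatial_index(co, "exact")
  p1 <- compute_patch_matrix(idx, 1)
  p2 <- compute_patch_matrix(idx, 3)
  raw <- drop_degenerate_features(sim$expression)$expr
  expect_error(
    permutation_null(raw, co, p1, p2, n_perm = 50),
    "at least 100")
  n1 <- permutation_null(raw, co, p1, p2, n_perm = 150, seed = 42)
  n2 <- permutation_null(raw, co, p1, p2, n_perm = 150, seed = 42)
  expect_identical(n1$ratios, n2$ratios)

  # patterned features clear the permutation null's 95th percentile
  scl <- scale_expression_maxabs(raw)$expr
  vr <- compute_variance_ratio(raw, scl, p1, p2)
  svf_ratios <- vr$ratio[grepl("^svf", vr$feature_id)]
  expect_gt(mean(svf_ratios > quantile(n1$ratios, 0.95)), 0.5)

  # lognormal and permutation p-values agree on rank order
  ln <- fit_lognormal_null(vr$ratio[!vr$excluded])
  p_ln <- compute_pvalues(vr$ratio, ln)
  p_pm <- compute_pvalues(vr$ratio, n1)
  expect_gte(cor(p_ln, p_pm, method = "spearman"), 0.99)
})

test_that("run_bsp validates radii and orders rows by input feature", {
  sim <- simulate_2d("streak", n_svf = 20, n_null = 180, fc = 4,
                     tau2 = 0.2, seed = 8)
  expect_error(run_bsp(sim$expression, sim$coords, r1 = 3, r2 = 3),
               "r1 < r2")
  res <- run_bsp(sim$expression, sim$coords, seed = 8)
  expect_identical(res$feature_id, sim$expression$feature_ids)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$ratio[res$excluded] == 0))
  expect_true(all(res$p_value[res$excluded] == 1))
  # BH adjustment adds a monotone q-value column
  resq <- run_bsp(sim$expression, sim$coords, seed = 8, adjust = "bh")
  expect_true(all(resq$q_value >= resq$p_value - 1e-12))
})

test_that("jointly shuffling spots leaves every p-value unchanged", {
  sim <- simulate_2d("annulus", n_svf = 25, n_null = 225, fc = 3,
                     tau2 = 0.5, seed = 13)
  res <- run_bsp(sim$expression, sim$coords, seed = 13)
  set.seed(99)
  perm <- sample(ncol(sim$expression$values))
  expr2 <- expression_matrix(sim$expression$values[, perm],
                             sim$expression$feature_ids)
  co2 <- spatial_coordinates(sim$coords$positions[perm, ],
                             sim$coords$spot_ids[perm])
  res2 <- run_bsp(expr2, co2, seed = 13)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res2$ratio, res$ratio, tolerance = 1e-12)
})

test_that("permuting feature order permutes the output rows accordingly", {
  sim <- simulate_2d("hotspot", n_svf = 25, n_null = 225, fc = 3,
                     tau2 = 0.2, seed = 17)
  res <- run_bsp(sim$expression, sim$coords, seed = 17)
  set.seed(1)
  fperm <- sample(nrow(sim$expression$values))
  expr2 <- expression_matrix(sim$expression$values[fperm, ],
                             sim$expression$feature_ids[fperm])
  res2 <- run_bsp(expr2, sim$coords, seed = 17)
  m <- match(res$feature_id, res2$feature_id)
  expect_equal(res2$p_value[m], res$p_value, tolerance = 1e-12)
})

test_that("pipeline matches the independent dense oracle", {
  for (s in 1:8) {
    inst <- random_instance(1000 + s, max_m = 120L, max_n = 40L)
    res <- run_bsp(expression_matrix(inst$X),
                   spatial_coordinates(inst$pos), seed = s)
    orc <- oracle_pipeline(inst$X, inst$pos)
    expect_equal(res$ratio, orc$ratio, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p_value, tolerance = 1e-10)
    expect_equal(res$weight, orc$weight, tolerance = 1e-10)
    expect_identical(res$excluded, orc$excluded)
  }
  # the sample-variance and scaled-weight switches match the oracle too
  inst <- random_instance(77)
  res <- run_bsp(expression_matrix(inst$X), spatial_coordinates(inst$pos),
                 variance_denominator = "sample", weight_on_scaled = TRUE)
  orc <- oracle_pipeline(inst$X, inst$pos, weight_on_scaled = TRUE,
                         denominator = "sample")
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-10)
})

test_that("strong discrete 3D signal separates SVFs from nulls completely", {
  d <- simulate_3d_discrete(radius = 2, fc = 3, noise_sigma = 0,
                            n_svf = 40, n_null = 360, seed = 2)
  res <- run_bsp(d$expression, d$coords, seed = 2)
  svf_p <- res$p_value[d$labels == "svf"]
  null_p <- res$p_value[d$labels == "null"]
  expect_lt(max(svf_p), min(null_p))
})
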