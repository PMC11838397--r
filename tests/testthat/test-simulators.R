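test_that("every generator is bit-reproducible under a fixed seed", {
  a <- simulate_2d("hotspot", n_svf = 10, n_null = 20, seed = 3)
  b <- simulate_2d("hotspot", n_svf = 10, n_null = 20, seed = 3)
  expect_identical(as.matrix(a$expression$values),
                   as.matrix(b$expression$values))
  expect_identical(a$coords$positions, b$coords$positions)

  a <- simulate_3d_continuous("tissue_layer", n_svf = 5, n_null = 10,
                              seed = 4)
  b <- simulate_3d_continuous("tissue_layer", n_svf = 5, n_null = 10,
                              seed = 4)
  expect_identical(as.matrix(a$expression$values),
                   as.matrix(b$expression$values))

  a <- simulate_3d_discrete(n_svf = 5, n_null = 10, seed = 5)
  b <- simulate_3d_discrete(n_svf = 5, n_null = 10, seed = 5)
  expect_identical(as.matrix(a$expression$values),
                   as.matrix(b$expression$values))

  a <- simulate_sparse_random(100, 200, 0.01, seed = 6)
  b <- simulate_sparse_random(100, 200, 0.01, seed = 6)
  expect_identical(as.matrix(a$expression$values),
                   as.matrix(b$expression$values))
})

test_that("null features are spot-permutations of SVFs (equal multisets)", {
  sim <- simulate_2d("streak", n_svf = 15, n_null = 30, fc = 4, seed = 7)
  X <- as.matrix(sim$expression$values)
  src <- sim$spec$null_sources
  for (q in seq_along(src)) {
    expect_equal(sort(X[15 + q, ]), sort(X[src[q], ]))
  }
  d3 <- simulate_3d_discrete(n_svf = 8, n_null = 16, noise_sigma = 1,
                             seed = 8)
  X3 <- as.matrix(d3$expression$values)
  for (q in seq_along(d3$spec$null_sources)) {
    expect_equal(sort(X3[8 + q, ]), sort(X3[d3$spec$null_sources[q], ]))
  }
})

test_that("2D generator hits the stated fold change and rejects bad input", {
  expect_error(simulate_2d(n_spots = 10), "at least 50")
  expect_error(simulate_2d(fc = 1), "exceed 1")
  # law of large numbers: empirical marked/unmarked mean ratio near fc.
  # E[y | marked] = fc * exp(beta_base + tau2/2), so the ratio estimates fc.
  sim <- simulate_2d("hotspot", n_spots = 2500, n_svf = 40, n_null = 10,
                     fc = 5, tau2 = 0.2, seed = 9)
  X <- as.matrix(sim$expression$values)[1:40, ]
  ratio <- mean(X[, sim$pattern_mask]) / mean(X[, !sim$pattern_mask])
  expect_lt(abs(ratio - 5) / 5, 0.1)
  # pattern mask is non-trivial
  expect_gt(sum(sim$pattern_mask), 0)
  expect_lt(sum(sim$pattern_mask), length(sim$pattern_mask))
})

test_that("3D continuous patterns have the stated geometry and monotonicity", {
  sim <- simulate_3d_continuous("curved_strand", n_svf = 5, n_null = 10,
                                seed = 10)
  expect_equal(nrow(sim$coords$positions), 2250L)
  for (s in 1:25) {
    layer <- simulate_3d_continuous("tissue_layer", n_svf = 2, n_null = 4,
                                    seed = s)
    steps <- diff(layer$spec$centers)
    monotone <- vapply(1:3, function(d) {
      all(steps[, d] >= 0) || all(steps[, d] <= 0)
    }, logical(1))
    expect_true(monotone[1])  # the constrained axis never reverses
    strand <- simulate_3d_continuous("curved_strand", n_svf = 2, n_null = 4,
                                     seed = s)
    st <- diff(strand$spec$centers)
    expect_true(all(st[, 1] >= 0) || all(st[, 1] <= 0))
    expect_true(all(st[, 2] >= 0) || all(st[, 2] <= 0))
  }
})

test_that("3D continuous marked/unmarked mean ratio approaches fc", {
  sim <- simulate_3d_continuous("irregular_aggregate", radius = 2.5,
                                fc = 3, noise_sigma = 0, n_svf = 50,
                                n_null = 10, seed = 11)
  X <- as.matrix(sim$expression$values)[1:50, ]
  ratio <- mean(X[, sim$pattern_mask]) / mean(X[, !sim$pattern_mask])
  expect_lt(abs(ratio - 3) / 3, 0.1)
})

test_that("3D discrete geometry: 9000 spots, 16 centers, oracle marked set", {
  sim <- simulate_3d_discrete(radius = 2, n_svf = 3, n_null = 6, seed = 12)
  expect_equal(nrow(sim$coords$positions), 9000L)
  expect_equal(dim(sim$spec$centers), c(16L, 3L))
  # brute-force point-in-sphere oracle
  pos <- sim$coords$positions
  oracle <- rep(FALSE, nrow(pos))
  for (ct in 1:16) {
    oracle <- oracle |
      (sqrt(colSums((t(pos) - sim$spec$centers[ct, ])^2)) <= 2)
  }
  expect_identical(sim$pattern_mask, unname(oracle))
  # zero jitter puts centers exactly on the stated grid at z = 5.5
  nj <- simulate_3d_discrete(center_jitter = 0, n_svf = 3, n_null = 6,
                             seed = 13)
  expect_equal(sort(unique(nj$spec$centers[, 1])), c(3, 11, 19, 27))
  expect_true(all(nj$spec$centers[, 3] == 5.5))
})

test_that("dropout zeroes exactly floor(rate * M) whole spots", {
  sim <- simulate_2d("hotspot", n_spots = 100, n_svf = 10, n_null = 20,
                     seed = 14)
  expect_error(apply_dropout(sim, 0), "in \\(0, 1\\)")
  expect_error(apply_dropout(sim, 1.2), "in \\(0, 1\\)")
  out <- apply_dropout(sim, 0.13, seed = 15)
  expect_length(out$spec$dropout_spots, 13L)
  X <- as.matrix(out$expression$values)
  expect_true(all(X[, out$spec$dropout_spots] == 0))
  untouched <- setdiff(seq_len(100), out$spec$dropout_spots)
  expect_equal(X[, untouched],
               as.matrix(sim$expression$values)[, untouched])
})

test_that("inter-plane stretch scales z only", {
  pos <- as.matrix(expand.grid(x = 1:3, y = 1:3, z = 0:9))
  co <- spatial_coordinates(pos)
  out <- stretch_interplane(co, 10)
  expect_equal(sort(unique(out$positions[, 3])), seq(0, 90, 10))
  expect_equal(out$positions[, 1:2], co$positions[, 1:2])
  # within-plane pairwise distances unchanged
  plane <- which(pos[, 3] == 4)
  expect_equal(unname(as.matrix(dist(out$positions[plane, 1:2]))),
               unname(as.matrix(dist(pos[plane, 1:2]))))
  expect_equal(stretch_interplane(co, 1)$positions, co$positions)
  expect_error(stretch_interplane(spatial_coordinates(pos[1:9, 1:2])),
               "3D")
})

test_that("sparse generator draws floor(1 + 10 Beta(1,5)) values", {
  expect_error(simulate_sparse_random(10, 10, 0), "density")
  d <- simulate_sparse_random(1000, 1000, 5e-4, seed = 16)
  vals <- d$expression$values@x
  expect_true(all(vals %in% 1:10))
  # binomial concentration of the non-zero count around 500
  expect_lt(abs(length(vals) - 500), 4 * sqrt(500))
  # Monte-Carlo oracle for the non-zero mean
  set.seed(17)
  mc <- floor(1 + 10 * rbeta(1e6, 1, 5))
  big <- simulate_sparse_random(300, 1000, 0.05, seed = 18)$expression$values@x
  se <- sd(mc) / sqrt(length(big))
  expect_lt(abs(mean(big) - mean(mc)), 3 * se + 3 * sd(mc) / sqrt(1e6))
})
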