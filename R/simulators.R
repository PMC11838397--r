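#' @rdname simulate_2d
#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset (%s): %d features x %d spots, %d SVF / %d null, %d marked spots\n",
    x$spec$family, nrow(x$expression$values), ncol(x$expression$values),
    sum(x$labels == "svf"), sum(x$labels == "null"), sum(x$pattern_mask)))
  invisible(x)
}

new_simulated_dataset <- function(expression, coords, labels, pattern_mask,
                                  spec) {
  stopifnot(length(labels) == nrow(expression$values),
            length(pattern_mask) == ncol(expression$values))
  if (!any(pattern_mask) || all(pattern_mask)) {
    stop("degenerate pattern: ", sum(pattern_mask), " of ",
         length(pattern_mask), " spots marked", call. = FALSE)
  }
  structure(
    list(expression = expression, coords = coords, labels = labels,
         pattern_mask = pattern_mask, spec = spec),
    class = "simulated_dataset"
  )
}

with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# null features as spot-permutations of the SVF rows (identical value
# multisets, no spatial pattern); sources drawn with replacement
permuted_nulls <- function(svf_mat, n_null) {
  M <- ncol(svf_mat)
  src <- sample.int(nrow(svf_mat), n_null, replace = TRUE)
  out <- svf_mat[src, , drop = FALSE]
  for (q in seq_len(n_null)) out[q, ] <- out[q, sample.int(M)]
  list(mat = out, source = src)
}

#' Simulate a 2D patterned spatial expression dataset
#'
#' Spots are placed on a jittered 2D lattice; a geometric mask (disk hotspot,
#' diagonal streak, or annulus) marks the patterned region. SVF counts follow
#' a log-normal-Poisson model per spot,
#' \deqn{y \sim \mathrm{Pois}(\lambda), \quad
#'       \ln\lambda = \beta_0 + \ln(\mathrm{FC})\,1[\mathrm{marked}] +
#'       \epsilon, \quad \epsilon \sim N(0, \tau^2),}
#' so the fold change FC is the marked/unmarked mean-expression ratio and
#' \eqn{\tau^2} the overdispersion. Null features are spot-permutations of
#' the SVFs.
#'
#' @param pattern `"hotspot"`, `"streak"` or `"annulus"`.
#' @param n_spots number of spots (default 260).
#' @param n_svf,n_null feature counts (defaults 1000 and 9000).
#' @param fc fold change between marked and unmarked mean expression
#'   (typical settings 3, 4, 5).
#' @param tau2 dispersion of the log-intensity noise (typical 0.2, 0.5, 0.8).
#' @param beta_base baseline log intensity; default `log(2)` (mean count 2
#'   outside the pattern before dispersion).
#' @param jitter half-width of the uniform lattice jitter (default 0.15
#'   lattice units).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a `simulated_dataset` with expression, coordinates, per-feature
#'   labels (`"svf"`/`"null"`), per-spot pattern mask, and the full
#'   parameter record in `$spec`.
#' @export
simulate_2d <- function(pattern = c("hotspot", "streak", "annulus"),
                        n_spots = 260L, n_svf = 1000L, n_null = 9000L,
                        fc = 3, tau2 = 0.2, beta_base = log(2),
                        jitter = 0.15, seed = 1L) {
  pattern <- match.arg(pattern)
  if (n_spots < 50L) stop("n_spots must be at least 50", call. = FALSE)
  if (fc <= 1) stop("fc must exceed 1", call. = FALSE)
  with_seed(seed, {
    nx <- ceiling(sqrt(n_spots))
    ny <- ceiling(n_spots / nx)
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny))[seq_len(n_spots), ]
    pos <- as.matrix(g) + matrix(runif(2L * n_spots, -jitter, jitter),
                                 ncol = 2L)
    ctr <- c(mean(range(pos[, 1L])), mean(range(pos[, 2L])))
    span <- min(diff(range(pos[, 1L])), diff(range(pos[, 2L])))
    rad <- sqrt((pos[, 1L] - ctr[1L])^2 + (pos[, 2L] - ctr[2L])^2)
    mask <- switch(pattern,
      hotspot = rad < 0.22 * span,
      streak = abs((pos[, 1L] - min(pos[, 1L])) -
                   (pos[, 2L] - min(pos[, 2L]))) < 0.12 * span,
      annulus = rad >= 0.25 * span & rad < 0.40 * span
    )
    if (!any(mask)) {
      stop("pattern mask is empty for this geometry", call. = FALSE)
    }
    beta <- beta_base + log(fc) * mask
    svf <- matrix(0, n_svf, n_spots)
    for (q in seq_len(n_svf)) {
      lam <- exp(beta + rnorm(n_spots, 0, sqrt(tau2)))
      svf[q, ] <- rpois(n_spots, lam)
    }
    nulls <- permuted_nulls(svf, n_null)
    expr <- expression_matrix(
      rbind(svf, nulls$mat),
      c(paste0("svf_", seq_len(n_svf)), paste0("null_", seq_len(n_null)))
    )
    coords <- spatial_coordinates(pos)
    new_simulated_dataset(
      expr, coords,
      labels = rep(c("svf", "null"), c(n_svf, n_null)),
      pattern_mask = mask,
      spec = list(family = "2d", pattern = pattern, n_spots = n_spots,
                  n_svf = n_svf, n_null = n_null, fc = fc, tau2 = tau2,
                  beta_base = beta_base, jitter = jitter, seed = seed,
                  null_sources = nulls$source)
    )
  })
}

# right-skewed reference count pool (negative binomial) and its upper
# quantile, with a scale factor pinning the marked/unmarked mean ratio to fc
reference_pools <- function(fc, upper_q, nb_mean, nb_size, pool_size = 1e4L) {
  pool <- rnbinom(pool_size, mu = nb_mean, size = nb_size)
  upper <- pool[pool >= stats::quantile(pool, upper_q)]
  scale <- fc * mean(pool) / mean(upper)
  list(pool = pool, upper = upper, scale = scale)
}

sample_pattern_expression <- function(mask, n_svf, n_null, fc, noise_sigma,
                                      upper_q, nb_mean, nb_size) {
  M <- length(mask)
  pools <- reference_pools(fc, upper_q, nb_mean, nb_size)
  svf <- matrix(0, n_svf, M)
  n_marked <- sum(mask)
  for (q in seq_len(n_svf)) {
    svf[q, !mask] <- sample(pools$pool, M - n_marked, replace = TRUE)
    svf[q, mask] <- sample(pools$upper, n_marked, replace = TRUE) *
      pools$scale
  }
  if (noise_sigma > 0) {
    avg_sd <- mean(apply(svf, 1L, sd))
    svf <- pmax(svf + matrix(rnorm(length(svf), 0, noise_sigma * avg_sd),
                             nrow = n_svf), 0)
  }
  nulls <- permuted_nulls(svf, n_null)
  list(svf = svf, nulls = nulls)
}

walk_centers <- function(start, n_steps, step_len, monotone_axes, lo, hi) {
  D <- length(start)
  centers <- matrix(0, n_steps + 1L, D)
  centers[1L, ] <- start
  # monotone axes move toward the farther wall so the walk has room
  signs <- ifelse(start - lo < hi - start, 1, -1)
  for (s in seq_len(n_steps)) {
    dir <- rnorm(D)
    dir <- dir / sqrt(sum(dir^2))
    if (length(monotone_axes)) {
      dir[monotone_axes] <- signs[monotone_axes] * abs(dir[monotone_axes])
    }
    nxt <- centers[s, ] + step_len * dir
    for (d in seq_len(D)) {
      if (d %in% monotone_axes) {
        # clamp: reflection would reverse the monotone direction
        nxt[d] <- min(max(nxt[d], lo[d]), hi[d])
      } else {
        if (nxt[d] < lo[d]) nxt[d] <- lo[d] + (lo[d] - nxt[d])
        if (nxt[d] > hi[d]) nxt[d] <- hi[d] - (nxt[d] - hi[d])
      }
    }
    centers[s + 1L, ] <- nxt
  }
  centers
}

mark_near_centers <- function(pos, centers, radius) {
  mask <- rep(FALSE, nrow(pos))
  for (ct in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(pos, 2L, centers[ct, ])^2)
    mask <- mask | d2 <= radius^2
  }
  unname(mask)
}

#' Simulate a 3D continuous-pattern dataset
#'
#' The tissue is 10 cryo-section planes (z = 1..10) of a 15 x 15 unit grid
#' (2,250 spots). The pattern is a union of spheres whose centers follow a
#' random walk with fixed step length 2; the walk's monotonicity sets the
#' pattern class: `curved_strand` is monotone in two axes, `tissue_layer` in
#' one, `irregular_aggregate` in none. Marked spots (inside any sphere) draw
#' counts from the upper quantile of a right-skewed negative-binomial
#' reference pool, scaled so the marked/unmarked mean ratio equals `fc`;
#' unmarked spots draw from the full pool. Gaussian noise with sd
#' `noise_sigma` times the average feature sd is added and truncated at
#' zero. Null features are spot-permutations of the SVFs.
#'
#' @param pattern `"curved_strand"`, `"tissue_layer"` or
#'   `"irregular_aggregate"`.
#' @param radius sphere radius (typical 1.5, 2.0, 2.5).
#' @param fc marked/unmarked mean fold change (typical 2.0, 2.5, 3.0).
#' @param noise_sigma noise level as a multiple of the average feature sd
#'   (typical 0, 1, 2).
#' @param n_svf,n_null feature counts (defaults 1000 and 9000).
#' @param n_steps random-walk steps (default 12).
#' @param nb_mean,nb_size negative-binomial reference pool parameters
#'   (defaults mean 2, size 2).
#' @param upper_q lower bound of the "upper quantile" sampled for marked
#'   spots (default 0.75, i.e. the top quartile).
#' @param seed integer seed.
#' @return a `simulated_dataset`; `$spec$centers` records the walk.
#' @export
simulate_3d_continuous <- function(pattern = c("curved_strand",
                                               "tissue_layer",
                                               "irregular_aggregate"),
                                   radius = 2.0, fc = 2.5, noise_sigma = 1,
                                   n_svf = 1000L, n_null = 9000L,
                                   n_steps = 12L, nb_mean = 2, nb_size = 2,
                                   upper_q = 0.75, seed = 1L) {
  pattern <- match.arg(pattern)
  with_seed(seed, {
    g <- expand.grid(x = seq_len(15L), y = seq_len(15L), z = seq_len(10L))
    pos <- as.matrix(g)
    lo <- c(1, 1, 1); hi <- c(15, 15, 10)
    monotone_axes <- switch(pattern,
      curved_strand = c(1L, 2L),
      tissue_layer = 1L,
      irregular_aggregate = integer(0)
    )
    start <- lo + runif(3L) * (hi - lo)
    centers <- walk_centers(start, n_steps, 2, monotone_axes, lo, hi)
    mask <- mark_near_centers(pos, centers, radius)
    if (!any(mask)) {
      stop("radius ", radius, " marks no spot; increase it", call. = FALSE)
    }
    sim <- sample_pattern_expression(mask, n_svf, n_null, fc, noise_sigma,
                                     upper_q, nb_mean, nb_size)
    expr <- expression_matrix(
      rbind(sim$svf, sim$nulls$mat),
      c(paste0("svf_", seq_len(n_svf)), paste0("null_", seq_len(n_null)))
    )
    new_simulated_dataset(
      expr, spatial_coordinates(pos),
      labels = rep(c("svf", "null"), c(n_svf, n_null)),
      pattern_mask = mask,
      spec = list(family = "3d_continuous", pattern = pattern,
                  radius = radius, fc = fc, noise_sigma = noise_sigma,
                  n_svf = n_svf, n_null = n_null, n_steps = n_steps,
                  nb_mean = nb_mean, nb_size = nb_size, upper_q = upper_q,
                  seed = seed, centers = centers,
                  null_sources = sim$nulls$source)
    )
  })
}

#' Simulate the 3D discrete isolated-nodule dataset
#'
#' 10 planes (z = 1..10) of a 30 x 30 unit grid (9,000 spots). Sixteen
#' sphere centers sit on the regular x,y grid \{3, 11, 19, 27\}^2 (8 units
#' apart) at z = 5.5, each jittered by U(-2, 2) per coordinate; marked spots
#' lie inside any sphere of the given radius. Expression follows the same
#' marked/unmarked sampling scheme as [simulate_3d_continuous()].
#'
#' @inheritParams simulate_3d_continuous
#' @param center_jitter half-width of the uniform center jitter; set 0 to
#'   place centers exactly on the stated grid.
#' @return a `simulated_dataset`; `$spec$centers` records the 16 jittered
#'   centers.
#' @export
simulate_3d_discrete <- function(radius = 2.0, fc = 3.0, noise_sigma = 0,
                                 n_svf = 1000L, n_null = 9000L,
                                 nb_mean = 2, nb_size = 2, upper_q = 0.75,
                                 center_jitter = 2, seed = 1L) {
  with_seed(seed, {
    g <- expand.grid(x = seq_len(30L), y = seq_len(30L), z = seq_len(10L))
    pos <- as.matrix(g)
    base <- as.matrix(expand.grid(x = seq(3, 27, by = 8),
                                  y = seq(3, 27, by = 8)))
    centers <- cbind(base, z = 5.5) +
      matrix(runif(16L * 3L, -center_jitter, center_jitter), ncol = 3L)
    mask <- mark_near_centers(pos, centers, radius)
    if (!any(mask)) {
      stop("radius ", radius, " marks no spot; increase it", call. = FALSE)
    }
    sim <- sample_pattern_expression(mask, n_svf, n_null, fc, noise_sigma,
                                     upper_q, nb_mean, nb_size)
    expr <- expression_matrix(
      rbind(sim$svf, sim$nulls$mat),
      c(paste0("svf_", seq_len(n_svf)), paste0("null_", seq_len(n_null)))
    )
    new_simulated_dataset(
      expr, spatial_coordinates(pos),
      labels = rep(c("svf", "null"), c(n_svf, n_null)),
      pattern_mask = mask,
      spec = list(family = "3d_discrete", radius = radius, fc = fc,
                  noise_sigma = noise_sigma, n_svf = n_svf, n_null = n_null,
                  nb_mean = nb_mean, nb_size = nb_size, upper_q = upper_q,
                  center_jitter = center_jitter, seed = seed,
                  centers = centers, null_sources = sim$nulls$source)
    )
  })
}

#' Zero out a random subset of spots (dropout perturbation)
#'
#' Selects exactly `floor(rate * M)` spots without replacement and sets all
#' features to zero there, emulating whole-spot capture failure.
#'
#' @param data a `simulated_dataset`.
#' @param rate fraction of spots to zero, in (0, 1); 0.10-0.30 are the
#'   benchmark settings.
#' @param seed integer seed for the spot selection.
#' @return the perturbed `simulated_dataset`; the zeroed spot indices are
#'   appended to `$spec$dropout_spots`.
#' @export
apply_dropout <- function(data, rate, seed = 1L) {
  stopifnot(inherits(data, "simulated_dataset"))
  if (!(rate > 0 && rate < 1)) {
    stop("dropout rate must be in (0, 1)", call. = FALSE)
  }
  M <- ncol(data$expression$values)
  n_drop <- floor(rate * M)
  with_seed(seed, {
    drop_idx <- sample.int(M, n_drop)
    X <- data$expression$values
    X[, drop_idx] <- 0
    data$expression <- expression_matrix(Matrix::drop0(X),
                                         data$expression$feature_ids,
                                         scaled = data$expression$scaled)
    data$spec$dropout_rate <- rate
    data$spec$dropout_seed <- seed
    data$spec$dropout_spots <- sort(drop_idx)
    data
  })
}

#' Stretch the z-axis to emulate coarse inter-plane resolution
#'
#' Multiplies the z coordinate by `factor`, leaving x and y (and so all
#' within-plane distances) untouched. Models serial sections spaced much
#' further apart than the within-section spot pitch.
#'
#' @param coords a 3D [spatial_coordinates()].
#' @param factor stretch factor, default 10.
#' @return the stretched [spatial_coordinates()].
#' @export
stretch_interplane <- function(coords, factor = 10) {
  stopifnot(inherits(coords, "spatial_coordinates"))
  if (ncol(coords$positions) != 3L) {
    stop("inter-plane stretch requires 3D coordinates", call. = FALSE)
  }
  coords$positions[, 3L] <- coords$positions[, 3L] * factor
  coords
}

#' Simulate a large sparse random count matrix
#'
#' Each entry is non-zero independently with probability `density`; non-zero
#' values are drawn as \eqn{\lfloor 1 + 10\,\mathrm{Beta}(1,5) \rfloor}
#' (integers in 1..10, right-skewed). Coordinates are uniform on a square of
#' side `sqrt(n_spots)` and left unrescaled. This is the throughput /
#' sparse-path stress generator: it has no spatial signal.
#'
#' @param n_features,n_spots matrix dimensions.
#' @param density probability an entry is non-zero, in (0, 1].
#' @param seed integer seed.
#' @return list with `expression` ([expression_matrix()]), `coords`
#'   (raw [spatial_coordinates()]) and `spec`.
#' @export
simulate_sparse_random <- function(n_features, n_spots, density, seed = 1L) {
  if (!(density > 0 && density <= 1)) {
    stop("density must be in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    total <- as.double(n_features) * n_spots
    if (total > 2^31 - 1) {
      stop("matrix too large for this generator (> 2^31 - 1 cells)",
           call. = FALSE)
    }
    k <- rbinom(1L, as.integer(total), density)
    cells <- sample.int(as.integer(total), k)
    ii <- ((cells - 1L) %% n_features) + 1L
    jj <- ((cells - 1L) %/% n_features) + 1L
    vals <- floor(1 + 10 * rbeta(k, 1, 5))
    X <- Matrix::sparseMatrix(i = ii, j = jj, x = vals,
                              dims = c(n_features, n_spots))
    side <- sqrt(n_spots)
    pos <- cbind(x = runif(n_spots, 0, side), y = runif(n_spots, 0, side))
    list(
      expression = expression_matrix(X),
      coords = spatial_coordinates(pos),
      spec = list(family = "sparse_random", n_features = n_features,
                  n_spots = n_spots, density = density, seed = seed)
    )
  })
}
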