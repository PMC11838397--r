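# Independent dense brute-force implementation of the full pipeline.
# Deliberately naive: dense matrices, an all-pairs distance matrix, explicit
# loops. Used only as the reference the sparse implementation must match.

oracle_popvar <- function(v) mean((v - mean(v))^2)

oracle_pipeline <- function(X, pos, r1 = 1, r2 = 3,
                            weight_on_scaled = FALSE,
                            denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  vfun <- if (denominator == "population") oracle_popvar else stats::var
  X <- as.matrix(X)
  M <- nrow(pos); D <- ncol(pos); N <- nrow(X)

  rng <- apply(pos, 2, function(v) max(v) - min(v))
  sp <- pos * (M / prod(rng))^(1 / D)
  dd <- as.matrix(stats::dist(sp))

  raw_var <- apply(X, 1, vfun)
  keep <- raw_var > 0
  Xk <- X[keep, , drop = FALSE]
  Xs <- Xk / apply(Xk, 1, max)

  patch <- function(r) {
    B <- dd < r
    diag(B) <- FALSE
    for (i in seq_len(M)) if (!any(B[, i])) B[i, i] <- TRUE
    B
  }
  local_means <- function(B) {
    out <- matrix(0, nrow(Xs), M)
    for (i in seq_len(M)) {
      members <- which(B[, i])
      out[, i] <- rowMeans(Xs[, members, drop = FALSE])
    }
    out
  }
  v1 <- apply(local_means(patch(r1)), 1, vfun)
  v2 <- apply(local_means(patch(r2)), 1, vfun)
  wbase <- if (weight_on_scaled) apply(Xs, 1, vfun) else raw_var[keep]
  w <- wbase / max(wbase)
  ratio <- ifelse(v1 > 0, w * v2 / v1, 0)
  excluded_k <- v1 <= 0 | ratio <= 0
  ratio[excluded_k] <- 0

  l <- log(ratio[!excluded_k])
  mu <- mean(l)
  s <- sqrt(sum((l - mu)^2) / (length(l) - (denominator == "sample")))
  pk <- rep(1, length(ratio))
  pk[!excluded_k] <- pmax(
    stats::pnorm((log(ratio[!excluded_k]) - mu) / s, lower.tail = FALSE),
    .Machine$double.xmin)

  full <- function(vals, fill) {
    out <- rep(fill, N)
    out[keep] <- vals
    out
  }
  data.frame(
    raw_variance = apply(X, 1, vfun),
    weight = full(w, 0),
    ratio = full(ratio, 0),
    p_value = full(pk, 1),
    excluded = full(excluded_k, TRUE),
    mu = mu, s = s
  )
}

# brute-force strict-radius neighbor membership (column i = patch of i)
oracle_patch_matrix <- function(pos, r) {
  dd <- as.matrix(stats::dist(pos))
  B <- dd < r
  diag(B) <- FALSE
  for (i in seq_len(nrow(pos))) if (!any(B[, i])) B[i, i] <- TRUE
  storage.mode(B) <- "double"
  unname(B)
}

random_instance <- function(seed, max_m = 200L, max_n = 50L) {
  set.seed(seed)
  M <- sample(20:max_m, 1)
  N <- sample(10:max_n, 1)
  D <- sample(2:3, 1)
  pos <- matrix(runif(M * D, 0, 10), M, D)
  X <- matrix(rpois(N * M, lambda = rexp(N * M, 1 / 2)), N, M)
  # ensure at least ten non-degenerate features so the lognormal fit runs
  X[1:10, ] <- matrix(rpois(10 * M, 3) + 1, 10, M)
  list(X = X, pos = pos, M = M, N = N, D = D)
}
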