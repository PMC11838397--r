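#' Per-feature big-small patch variance ratios
#'
#' For each feature j, computes the variance across spots of its local means
#' at the small and big radii, \eqn{\sigma^2_{j,1}} and \eqn{\sigma^2_{j,2}},
#' the weight \eqn{w_j = \sigma^2_j / \max_n \sigma^2_n} (relative overall
#' variance), and the test statistic
#' \deqn{r_j = w_j \, \sigma^2_{j,2} / \sigma^2_{j,1}.}
#' A feature whose expression survives coarse smoothing (big-patch variance
#' stays high relative to small-patch variance) has spatial structure and a
#' large \eqn{r_j}.
#'
#' Features whose small-patch local-mean variance is exactly zero (every
#' patch mean constant) would give an infinite ratio; they are flagged
#' `excluded` with `ratio = 0` instead.
#'
#' @param expr_raw the retained (non-degenerate) raw [expression_matrix()].
#' @param expr_scaled its max-abs scaled counterpart, same features.
#' @param patches_small,patches_big `patch_assignment`s at radii R1 < R2 on
#'   the same spot set.
#' @param weight_on_scaled compute the weight from the scaled matrix's
#'   variances instead of the raw matrix's (default raw).
#' @param variance_denominator `"population"` (divide by M, default) or
#'   `"sample"`; the ratio \eqn{\sigma^2_{j,2}/\sigma^2_{j,1}} and the weight
#'   are invariant to this choice, the fitted log-sd is not.
#' @return data frame with columns `feature_id`, `raw_variance`, `weight`,
#'   `ratio`, `var_small`, `var_big`, `excluded`.
#' @export
compute_variance_ratio <- function(expr_raw, expr_scaled,
                                   patches_small, patches_big,
                                   weight_on_scaled = FALSE,
                                   variance_denominator = c("population",
                                                            "sample")) {
  variance_denominator <- match.arg(variance_denominator)
  stopifnot(inherits(expr_raw, "expression_matrix"),
            inherits(expr_scaled, "expression_matrix"))
  if (!identical(expr_raw$feature_ids, expr_scaled$feature_ids)) {
    stop("raw and scaled matrices carry different feature sets", call. = FALSE)
  }
  raw_var <- row_variances(expr_raw$values, variance_denominator)
  wbase <- if (weight_on_scaled) {
    row_variances(expr_scaled$values, variance_denominator)
  } else raw_var
  w <- wbase / max(wbase)
  v1 <- row_variances(compute_local_means(expr_scaled, patches_small),
                      variance_denominator)
  v2 <- row_variances(compute_local_means(expr_scaled, patches_big),
                      variance_denominator)
  excluded <- v1 <= 0
  ratio <- ifelse(excluded, 0, w * v2 / pmax(v1, .Machine$double.xmin))
  data.frame(
    feature_id = expr_raw$feature_ids,
    raw_variance = raw_var,
    weight = w,
    ratio = ratio,
    var_small = v1,
    var_big = v2,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
}

#' Fit the lognormal null to a set of variance ratios
#'
#' Under the working assumption that only a minority of features are
#' spatially variable, the bulk of the ratios follows a lognormal law.
#' Gaussian maximum likelihood on the log ratios gives
#' \eqn{\hat\mu = \mathrm{mean}(\ln r)} and \eqn{\hat s = \mathrm{sd}(\ln r)}.
#' An optional trimmed fit drops the largest `trim` fraction of ratios
#' before fitting, as a guard against a heavy signal tail.
#'
#' @param ratios numeric vector; non-positive or non-finite entries are
#'   dropped before fitting.
#' @param variance_denominator `"population"` (MLE, divide by n; default) or
#'   `"sample"` for the log-sd.
#' @param trim fraction in `[0, 0.5)` of the largest ratios to drop; default
#'   0 (fit on all).
#' @return a `null_model` of kind `"lognormal"` with fields `mu`, `s`,
#'   `n_fit`.
#' @export
fit_lognormal_null <- function(ratios,
                               variance_denominator = c("population",
                                                        "sample"),
                               trim = 0) {
  variance_denominator <- match.arg(variance_denominator)
  stopifnot(trim >= 0, trim < 0.5)
  r <- ratios[is.finite(ratios) & ratios > 0]
  if (trim > 0) {
    r <- sort(r)[seq_len(ceiling(length(r) * (1 - trim)))]
  }
  if (length(r) < 10L) {
    stop("only ", length(r), " usable positive ratios (need >= 10); ",
         "use the permutation null for small feature panels", call. = FALSE)
  }
  l <- log(r)
  mu <- mean(l)
  s <- sqrt(sum((l - mu)^2) /
              (length(l) - (variance_denominator == "sample")))
  if (s == 0) {
    stop("degenerate lognormal fit: all ratios identical; ",
         "use the permutation null", call. = FALSE)
  }
  structure(list(kind = "lognormal", mu = mu, s = s, n_fit = length(l)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  if (x$kind == "lognormal") {
    cat(sprintf("null_model: lognormal, mu = %.4g, s = %.4g (n = %d)\n",
                x$mu, x$s, x$n_fit))
  } else {
    cat(sprintf("null_model: permutation, %d null ratios\n",
                length(x$ratios)))
  }
  invisible(x)
}

#' Upper-tail p-values for variance ratios under a fitted null
#'
#' Lognormal null: \eqn{p_j = 1 - \Phi((\ln r_j - \hat\mu)/\hat s)}.
#' Permutation null: the add-one empirical tail
#' \eqn{p_j = (1 + \#\{r^{null} \ge r_j\}) / (1 + n_{null})}.
#' Non-positive ratios get p = 1. All p-values lie in (0, 1].
#'
#' @param ratios numeric vector of test statistics.
#' @param null a `null_model` from [fit_lognormal_null()] or
#'   [permutation_null()].
#' @return numeric vector of p-values, same length as `ratios`.
#' @export
compute_pvalues <- function(ratios, null) {
  stopifnot(inherits(null, "null_model"))
  p <- rep(1, length(ratios))
  ok <- is.finite(ratios) & ratios > 0
  if (null$kind == "lognormal") {
    p[ok] <- pnorm((log(ratios[ok]) - null$mu) / null$s, lower.tail = FALSE)
  } else {
    nr <- null$ratios
    n <- length(nr)
    # add-one tail keeps p strictly positive and valid
    p[ok] <- (1 + vapply(ratios[ok], function(r) sum(nr >= r), numeric(1L))) /
      (1 + n)
  }
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Empirical null from spot-permuted features
#'
#' Destroys spatial structure while preserving each feature's value multiset:
#' `n_perm` features are drawn with replacement from the input, each is
#' independently permuted across spots, and the permuted panel is pushed
#' through the full statistic (max-abs scaling, local means at both radii,
#' weighting against `max_variance`). Recommended for low-throughput panels
#' where too few genuine non-SVFs exist to fit the lognormal.
#'
#' @param expr_raw the retained raw [expression_matrix()].
#' @param coords the rescaled [spatial_coordinates()] (spot set check only;
#'   the patches carry the geometry).
#' @param patches_small,patches_big the patch assignments used for the
#'   observed statistics.
#' @param n_perm number of permuted features, at least 100.
#' @param seed integer seed; the same seed reproduces the null exactly.
#' @param max_variance normalizing constant for the weight; defaults to the
#'   maximum per-feature variance of `expr_raw` so null and observed ratios
#'   share a scale.
#' @inheritParams compute_variance_ratio
#' @return a `null_model` of kind `"permutation"` with the sorted null
#'   ratios.
#' @export
permutation_null <- function(expr_raw, coords, patches_small, patches_big,
                             n_perm = 1000L, seed = 1L,
                             max_variance = NULL,
                             weight_on_scaled = FALSE,
                             variance_denominator = c("population",
                                                      "sample")) {
  variance_denominator <- match.arg(variance_denominator)
  if (n_perm < 100L) {
    stop("n_perm must be at least 100 for a usable empirical tail",
         call. = FALSE)
  }
  check_paired(expr_raw, coords)
  X <- expr_raw$values
  N <- nrow(X); M <- ncol(X)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  picks <- sample.int(N, n_perm, replace = TRUE)
  # permute the column indices of each drawn feature's nonzeros
  Xt <- Matrix::t(X)  # column-compressed by feature
  ptr <- Xt@p
  ii <- jj <- xx <- vector("list", n_perm)
  for (q in seq_len(n_perm)) {
    f <- picks[q]
    idx <- seq.int(ptr[f] + 1L, length.out = ptr[f + 1L] - ptr[f])
    if (!length(idx)) next
    ii[[q]] <- rep.int(q, length(idx))
    jj[[q]] <- sample.int(M, length(idx))
    xx[[q]] <- Xt@x[idx]
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_perm, M))
  perm <- expression_matrix(P, paste0("perm_", seq_len(n_perm)))
  keep <- row_variances(perm$values) > 0
  if (!any(keep)) {
    stop("all permuted features are constant; cannot build a null",
         call. = FALSE)
  }
  perm <- expression_matrix(perm$values[keep, , drop = FALSE],
                            perm$feature_ids[keep])
  scl <- scale_expression_maxabs(perm)$expr
  if (is.null(max_variance)) {
    max_variance <- max(row_variances(
      if (weight_on_scaled) scale_expression_maxabs(expr_raw)$expr$values
      else X, variance_denominator))
  }
  wbase <- row_variances(if (weight_on_scaled) scl$values else perm$values,
                         variance_denominator)
  w <- wbase / max_variance
  v1 <- row_variances(compute_local_means(scl, patches_small),
                      variance_denominator)
  v2 <- row_variances(compute_local_means(scl, patches_big),
                      variance_denominator)
  ok <- v1 > 0
  ratios <- w[ok] * v2[ok] / v1[ok]
  structure(list(kind = "permutation", ratios = sort(ratios),
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "null_model")
}

#' Run the full big-small patch SVF pipeline
#'
#' Rescales coordinates to unit spot density, max-abs scales expression,
#' drops degenerate (constant) features, builds patches at the small and big
#' radii, computes weighted variance ratios, fits the null, and assigns
#' one-sided upper-tail p-values. Rows are returned in input feature order;
#' excluded features carry `p_value = 1` and `ratio = 0`.
#'
#' @param expr an [expression_matrix()] (raw counts; no prior normalization
#'   expected or wanted).
#' @param coords the matching [spatial_coordinates()]; raw coordinates are
#'   rescaled internally, already-rescaled ones are used as-is.
#' @param r1,r2 small and big patch radii in rescaled units; defaults 1 and 3.
#' @param null_kind `"lognormal"` (default) or `"permutation"`.
#' @param n_perm permutation-null size (used only for `"permutation"`).
#' @param mode neighbor search mode, `"exact"` or `"approximate"`.
#' @param recall_target approximate-mode expected recall.
#' @param seed integer seed (permutation null and approximate grids).
#' @param alpha significance level for the `significant` call; p-values are
#'   always reported.
#' @param adjust `"none"` or `"bh"` for an extra Benjamini-Hochberg
#'   `q_value` column.
#' @param trim fraction of largest ratios dropped before the lognormal fit
#'   (default 0).
#' @inheritParams compute_variance_ratio
#' @return an `svf_result` data frame with columns `feature_id`,
#'   `raw_variance`, `weight`, `ratio`, `p_value`, `excluded`,
#'   `significant` (and `q_value` if requested); the fitted `null_model`
#'   and the run parameters are attached as attributes `null_model` and
#'   `params`.
#' @export
run_bsp <- function(expr, coords, r1 = 1.0, r2 = 3.0,
                    null_kind = c("lognormal", "permutation"),
                    n_perm = 1000L, mode = c("exact", "approximate"),
                    recall_target = 0.99, seed = 1L, alpha = 0.05,
                    adjust = c("none", "bh"), trim = 0,
                    weight_on_scaled = FALSE,
                    variance_denominator = c("population", "sample")) {
  null_kind <- match.arg(null_kind)
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  variance_denominator <- match.arg(variance_denominator)
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(coords, "spatial_coordinates"))
  if (!(r1 > 0 && r2 > r1)) {
    stop("radii must satisfy 0 < r1 < r2 (got r1 = ", r1, ", r2 = ", r2, ")",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  check_paired(expr, coords)

  if (!coords$is_rescaled) coords <- rescale_coordinates(coords)$coords
  dropped <- drop_degenerate_features(expr)
  raw <- dropped$expr
  scaled <- scale_expression_maxabs(raw)$expr
  index <- build_spatial_index(coords, mode = mode,
                               recall_target = recall_target, seed = seed)
  p1 <- compute_patch_matrix(index, r1)
  p2 <- compute_patch_matrix(index, r2)
  vr <- compute_variance_ratio(raw, scaled, p1, p2,
                               weight_on_scaled = weight_on_scaled,
                               variance_denominator = variance_denominator)
  # a zero ratio (flat big-patch means) carries no evidence either way;
  # route it to the exclusion report with p = 1 rather than feed the fit
  vr$excluded <- vr$excluded | vr$ratio <= 0
  vr$ratio[vr$excluded] <- 0
  usable <- !vr$excluded
  null <- if (null_kind == "lognormal") {
    fit_lognormal_null(vr$ratio[usable],
                       variance_denominator = variance_denominator,
                       trim = trim)
  } else {
    permutation_null(raw, coords, p1, p2, n_perm = n_perm, seed = seed,
                     weight_on_scaled = weight_on_scaled,
                     variance_denominator = variance_denominator)
  }
  pv <- rep(1, nrow(vr))
  pv[usable] <- compute_pvalues(vr$ratio[usable], null)

  # reassemble in input feature order, degenerate features included
  N <- length(expr$feature_ids)
  out <- data.frame(
    feature_id = expr$feature_ids,
    raw_variance = row_variances(expr$values, variance_denominator),
    weight = 0, ratio = 0, p_value = 1,
    excluded = TRUE, stringsAsFactors = FALSE
  )
  idx <- match(vr$feature_id, expr$feature_ids)
  out$weight[idx] <- vr$weight
  out$ratio[idx] <- vr$ratio
  out$p_value[idx] <- pv
  out$excluded[idx] <- vr$excluded
  out$significant <- !out$excluded & out$p_value < alpha
  if (adjust == "bh") {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  attr(out, "null_model") <- null
  attr(out, "params") <- list(
    r1 = r1, r2 = r2, null_kind = null_kind, n_perm = n_perm, mode = mode,
    recall_target = recall_target, seed = seed, alpha = alpha,
    adjust = adjust, trim = trim, weight_on_scaled = weight_on_scaled,
    variance_denominator = variance_denominator,
    n_features = N, n_spots = ncol(expr$values),
    n_excluded = sum(out$excluded)
  )
  class(out) <- c("svf_result", "data.frame")
  out
}
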