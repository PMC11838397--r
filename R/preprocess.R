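#' Rescale coordinates to unit spot density
#'
#' Multiplies all coordinates by the single isotropic factor
#' \eqn{(M / \prod_d \Delta s^{(d)})^{1/D}}, where \eqn{\Delta s^{(d)}} is the
#' coordinate range along dimension d. After rescaling the product of the
#' per-dimension ranges equals the number of spots M, so the average
#' spot-to-spot spacing is close to one unit and the default patch radii
#' (1 and 3) are meaningful. Being a similarity transform, the rescaling
#' preserves all distance ratios; anisotropic spacing (e.g. a stretched
#' z-axis) is preserved, not corrected.
#'
#' @param coords a raw [spatial_coordinates()] object.
#' @return a list with `coords` (rescaled, `is_rescaled = TRUE`) and `record`,
#'   a `rescale_record` holding the per-dimension ranges and the scalar
#'   factor.
#' @export
rescale_coordinates <- function(coords) {
  stopifnot(inherits(coords, "spatial_coordinates"))
  if (coords$is_rescaled) {
    stop("coordinates are already rescaled", call. = FALSE)
  }
  pos <- coords$positions
  M <- nrow(pos); D <- ncol(pos)
  ranges <- apply(pos, 2L, function(v) max(v) - min(v))
  if (any(ranges <= 0)) {
    dead <- colnames(pos)[ranges <= 0]
    stop("zero coordinate range in dimension(s) ",
         paste(dead, collapse = ", "),
         "; drop the degenerate dimension or jitter the positions",
         call. = FALSE)
  }
  factor <- (M / prod(ranges))^(1 / D)
  out <- coords
  out$positions <- pos * factor
  out$is_rescaled <- TRUE
  record <- structure(
    list(ranges = ranges, factor = factor, M = M, D = D),
    class = "rescale_record"
  )
  list(coords = out, record = record)
}

#' @export
print.rescale_record <- function(x, ...) {
  cat(sprintf("rescale_record: factor %.6g over ranges (%s), M = %d\n",
              x$factor, paste(signif(x$ranges, 6), collapse = ", "), x$M))
  invisible(x)
}

#' Max-absolute scaling of expression to [0, 1] per feature
#'
#' Divides each feature (row) by its maximum value so every non-empty row
#' attains 1 at its argmax. The sparsity pattern is unchanged and the
#' operation is idempotent. All-zero rows are left untouched and reported.
#'
#' @param expr an [expression_matrix()].
#' @return list with `expr` (scaled) and `all_zero`, the ids of all-zero
#'   features.
#' @export
scale_expression_maxabs <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  X <- expr$values
  row_max <- row_max_sparse(X)
  zero <- row_max == 0
  inv <- ifelse(zero, 1, 1 / row_max)
  Xs <- Matrix::Diagonal(x = inv) %*% X
  Xs <- as(Xs, "CsparseMatrix")
  dimnames(Xs) <- dimnames(X)
  list(expr = expression_matrix(Xs, expr$feature_ids, scaled = TRUE),
       all_zero = expr$feature_ids[zero])
}

# rowwise max of a non-negative dgCMatrix without densifying
row_max_sparse <- function(X) {
  out <- numeric(nrow(X))
  if (length(X@x)) {
    ri <- X@i + 1L
    mx <- vapply(split(X@x, ri), max, numeric(1L))
    out[as.integer(names(mx))] <- pmax(out[as.integer(names(mx))], mx)
  }
  out
}

# population (divide-by-M) or sample row variances of a sparse matrix
row_variances <- function(X, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  M <- ncol(X)
  s1 <- Matrix::rowSums(X)
  s2 <- Matrix::rowSums(X^2)
  v <- pmax(s2 / M - (s1 / M)^2, 0)
  if (denominator == "sample") v <- v * M / (M - 1)
  unname(v)
}

#' Drop features with zero variance across spots
#'
#' Constant features (including all-zero ones) have no spatial signal and
#' make the small-patch variance denominator undefined; they are moved to an
#' exclusion report and assigned `p_value = 1` downstream.
#'
#' @param expr an [expression_matrix()].
#' @return list with `expr` (retained features), `excluded` (ids) and
#'   `kept` (logical index into the input features).
#' @export
drop_degenerate_features <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- row_variances(expr$values)
  keep <- v > 0
  if (!any(keep)) {
    stop("all features are constant across spots; nothing to test",
         call. = FALSE)
  }
  list(
    expr = expression_matrix(expr$values[keep, , drop = FALSE],
                             expr$feature_ids[keep], scaled = expr$scaled),
    excluded = expr$feature_ids[!keep],
    kept = unname(keep)
  )
}
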