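#' @importFrom methods as is new
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t readMM writeMM
#' @importFrom stats pnorm qnorm rnorm rpois rnbinom rbeta runif sd var setNames
#' @importFrom utils write.csv
#' @useDynLib patchsvf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Spatial coordinates of spots
#'
#' Container for the spot positions of one sample: an `M x D` numeric matrix
#' (`D` = 2 or 3) plus unique spot identifiers. Positions may be in arbitrary
#' length units; [rescale_coordinates()] normalizes them to unit spot density
#' and flips `is_rescaled`.
#'
#' @param positions numeric matrix, one row per spot, 2 or 3 columns.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   `"spot_1" ... "spot_M"`.
#' @param is_rescaled logical; whether the positions are already
#'   density-rescaled. New raw data should leave this `FALSE`.
#' @return an object of class `spatial_coordinates`.
#' @export
spatial_coordinates <- function(positions, spot_ids = NULL, is_rescaled = FALSE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  D <- ncol(positions)
  M <- nrow(positions)
  if (!D %in% c(2L, 3L)) {
    stop("coordinates must have 2 or 3 dimensions, got ", D, call. = FALSE)
  }
  if (M < 2L) {
    stop("at least 2 spots are required (a single spot has no neighbors)",
         call. = FALSE)
  }
  if (!all(is.finite(positions))) {
    stop("coordinate entries must all be finite", call. = FALSE)
  }
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(M))
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != M) {
    stop("spot_ids length (", length(spot_ids), ") != number of spots (", M, ")",
         call. = FALSE)
  }
  if (anyDuplicated(spot_ids)) {
    stop("spot_ids must be unique", call. = FALSE)
  }
  rownames(positions) <- spot_ids
  colnames(positions) <- c("x", "y", "z")[seq_len(D)]
  structure(
    list(positions = positions, spot_ids = spot_ids,
         is_rescaled = isTRUE(is_rescaled)),
    class = "spatial_coordinates"
  )
}

#' @export
print.spatial_coordinates <- function(x, ...) {
  cat(sprintf("spatial_coordinates: %d spots x %d dims (%s)\n",
              nrow(x$positions), ncol(x$positions),
              if (x$is_rescaled) "rescaled" else "raw units"))
  invisible(x)
}

#' @export
dim.spatial_coordinates <- function(x) dim(x$positions)

#' Sparse features-by-spots expression matrix
#'
#' Container for a non-negative `N x M` expression (or accessibility) matrix,
#' stored sparse, with unique feature identifiers. The canonical in-memory
#' orientation is features-by-spots; readers normalize to it.
#'
#' @param values matrix-like, features in rows, spots in columns. Coerced to
#'   `dgCMatrix`.
#' @param feature_ids character vector of unique feature ids; defaults to
#'   `"feature_1" ...`.
#' @param scaled logical; `TRUE` marks a matrix already max-abs scaled to
#'   `[0, 1]` per feature.
#' @return an object of class `expression_matrix` with a `density` field,
#'   the fraction of stored non-zero entries.
#' @export
expression_matrix <- function(values, feature_ids = NULL, scaled = FALSE) {
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  N <- nrow(values); M <- ncol(values)
  if (length(values@x) && min(values@x) < 0) {
    stop("expression matrix must be non-negative", call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- if (!is.null(rownames(values))) rownames(values)
                   else paste0("feature_", seq_len(N))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != N) {
    stop("feature_ids length (", length(feature_ids),
         ") != number of features (", N, ")", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("feature_ids must be unique", call. = FALSE)
  }
  rownames(values) <- feature_ids
  structure(
    list(values = values, feature_ids = feature_ids,
         density = length(values@x) / (as.double(N) * M),
         scaled = isTRUE(scaled)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d spots, density %.3g%s\n",
              nrow(x$values), ncol(x$values), x$density,
              if (x$scaled) " (max-abs scaled)" else ""))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

check_paired <- function(expr, coords) {
  if (ncol(expr$values) != nrow(coords$positions)) {
    stop("expression has ", ncol(expr$values), " spots but coordinates have ",
         nrow(coords$positions), call. = FALSE)
  }
  invisible(TRUE)
}
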