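#' Build a spatial index over rescaled coordinates
#'
#' The index supports fixed-radius neighbor queries used to form patches.
#' `exact` mode uses a cell-list (grid) search that returns every pair at
#' distance strictly below the query radius. `approximate` mode generates
#' candidate pairs from randomly shifted grids and verifies distances, so
#' every returned neighbor is true but a small fraction can be missed; the
#' number of grid repetitions is chosen so the expected per-pair recall is
#' at least `recall_target`.
#'
#' Radius queries assume density-rescaled coordinates (the default radii 1
#' and 3 are in rescaled units); building on raw coordinates is an error
#' unless `allow_unrescaled = TRUE`.
#'
#' @param coords a rescaled [spatial_coordinates()].
#' @param mode `"exact"` or `"approximate"`.
#' @param recall_target expected per-pair recall for approximate mode,
#'   in (0, 1); default 0.99.
#' @param allow_unrescaled bypass the rescaling check (radii are then in the
#'   caller's raw units).
#' @param seed integer seed for the approximate mode's random grid shifts.
#' @return a `spatial_index` object.
#' @export
build_spatial_index <- function(coords, mode = c("exact", "approximate"),
                                recall_target = 0.99,
                                allow_unrescaled = FALSE, seed = 1L) {
  stopifnot(inherits(coords, "spatial_coordinates"))
  mode <- match.arg(mode)
  if (!coords$is_rescaled && !allow_unrescaled) {
    stop("coordinates are not density-rescaled; call rescale_coordinates() ",
         "first or pass allow_unrescaled = TRUE", call. = FALSE)
  }
  if (!(recall_target > 0 && recall_target < 1)) {
    stop("recall_target must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(positions = coords$positions, mode = mode,
         recall_target = recall_target, seed = as.integer(seed)),
    class = "spatial_index"
  )
}

#' @export
print.spatial_index <- function(x, ...) {
  cat(sprintf("spatial_index: %d spots, %s mode%s\n", nrow(x$positions),
              x$mode,
              if (x$mode == "approximate")
                sprintf(" (recall target %.3g)", x$recall_target) else ""))
  invisible(x)
}

# neighbor pairs (i < j, strict dist < r) as a two-column integer matrix
neighbor_pairs <- function(index, radius) {
  pos <- index$positions
  if (index$mode == "exact") {
    p <- .radius_pairs(pos, radius)
    return(cbind(i = p$i, j = p$j))
  }
  approx_pairs(pos, radius, index$recall_target, index$seed)
}

# shifted-grid candidate generation: T independent grids of cell side 2r with
# uniform random offsets; a pair at distance < r shares a cell with
# probability >= p_min = (1 - 1/(2*sqrt(D)))^D per grid, so T grids give
# per-pair recall >= 1 - (1 - p_min)^T. Candidates are distance-verified,
# hence no false members.
approx_pairs <- function(pos, radius, recall_target, seed) {
  M <- nrow(pos); D <- ncol(pos)
  p_min <- (1 - 1 / (2 * sqrt(D)))^D
  n_rep <- max(1L, ceiling(log(1 - recall_target) / log(1 - p_min)))
  side <- 2 * radius
  keys_seen <- new.env(hash = TRUE)
  acc_i <- integer(0); acc_j <- integer(0)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  for (rep in seq_len(n_rep)) {
    shift <- runif(D, 0, side)
    cells <- floor(sweep(pos, 2L, shift, "+") / side)
    key <- apply(cells, 1L, paste, collapse = ",")
    groups <- split(seq_len(M), key)
    for (g in groups) {
      n <- length(g)
      if (n < 2L) next
      d <- as.matrix(stats::dist(pos[g, , drop = FALSE]))
      hit <- which(d < radius & upper.tri(d), arr.ind = TRUE)
      if (nrow(hit)) {
        acc_i <- c(acc_i, g[hit[, 1L]])
        acc_j <- c(acc_j, g[hit[, 2L]])
      }
    }
  }
  if (!length(acc_i)) return(cbind(i = integer(0), j = integer(0)))
  ii <- pmin(acc_i, acc_j); jj <- pmax(acc_i, acc_j)
  keep <- !duplicated(ii * (M + 1) + jj)
  cbind(i = ii[keep], j = jj[keep])
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Compute the sparse binary patch matrix for one radius
#'
#' Column i of the returned `M x M` matrix marks the patch of center spot i:
#' the spots at distance strictly below `radius` from it, excluding the spot
#' itself. A spot with no neighbors within the radius falls back to a patch
#' containing only itself (a diagonal 1), so every column is non-empty.
#'
#' @param index a `spatial_index` from [build_spatial_index()].
#' @param radius patch radius, in the units of the indexed coordinates.
#' @return a `patch_assignment`: list with `membership` (sparse `dgCMatrix`),
#'   `radius` and `mode`.
#' @export
compute_patch_matrix <- function(index, radius) {
  stopifnot(inherits(index, "spatial_index"))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a single positive number", call. = FALSE)
  }
  M <- nrow(index$positions)
  p <- neighbor_pairs(index, radius)
  B <- Matrix::sparseMatrix(
    i = c(p[, 1L], p[, 2L]), j = c(p[, 2L], p[, 1L]),
    x = 1, dims = c(M, M)
  )
  empty <- which(Matrix::colSums(B) == 0)
  if (length(empty)) {
    B <- B + Matrix::sparseMatrix(i = empty, j = empty, x = 1,
                                  dims = c(M, M))
  }
  structure(
    list(membership = as(B, "CsparseMatrix"), radius = radius,
         mode = index$mode),
    class = "patch_assignment"
  )
}

#' @export
print.patch_assignment <- function(x, ...) {
  cat(sprintf(
    "patch_assignment: %d spots, radius %.3g, %s mode, mean patch size %.2f\n",
    ncol(x$membership), x$radius, x$mode,
    mean(Matrix::colSums(x$membership))))
  invisible(x)
}

#' Local mean expression over patches
#'
#' Computes the patch-averaged (local mean) expression at each spot,
#' \eqn{\bar X^{(k)} = \tilde X B^{(k)} D}, where D is the diagonal matrix of
#' inverse patch sizes. Entry (j, i) is the mean scaled expression of
#' feature j over the patch of spot i. The product is carried out on sparse
#' matrices; the patch matrix is never densified.
#'
#' @param expr_scaled a max-abs scaled [expression_matrix()].
#' @param patches a `patch_assignment` on the same spot set.
#' @return a sparse `N x M` matrix of local means, entries in `[0, 1]`.
#' @export
compute_local_means <- function(expr_scaled, patches) {
  stopifnot(inherits(expr_scaled, "expression_matrix"),
            inherits(patches, "patch_assignment"))
  B <- patches$membership
  if (ncol(expr_scaled$values) != ncol(B)) {
    stop("expression has ", ncol(expr_scaled$values),
         " spots but patches have ", ncol(B), call. = FALSE)
  }
  sizes <- Matrix::colSums(B)
  Xbar <- expr_scaled$values %*% B %*% Matrix::Diagonal(x = 1 / sizes)
  as(Xbar, "CsparseMatrix")
}
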