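#' Read an expression matrix from disk
#'
#' Reads a features-by-spots (or spots-by-features, see `orientation`)
#' non-negative matrix from Matrix Market or delimited text and returns it in
#' the canonical features-by-spots orientation.
#'
#' Matrix Market files use 1-based indices on disk (the MTX standard); the
#' in-memory `dgCMatrix` is 0-based internally, the translation is handled by
#' `Matrix::readMM`. In `mtx` mode two plain-text sidecars, one name per line,
#' supply the row and column identifiers: `<stem>.rownames.txt` and
#' `<stem>.colnames.txt` next to the matrix file (or pass explicit paths).
#'
#' @param path file path to the matrix (`.mtx`, `.csv` or `.tsv`). Delimited
#'   files carry a header of spot (or feature) ids and feature (or spot) ids
#'   in the first column.
#' @param fmt `"mtx"`, `"csv"` or `"tsv"`; default guessed from the extension.
#' @param orientation `"features_by_spots"` (default) or `"spots_by_features"`;
#'   how the file is laid out on disk. The result is always features x spots.
#' @param row_names,col_names optional sidecar paths for `mtx` mode.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path,
                            fmt = c("guess", "mtx", "csv", "tsv"),
                            orientation = c("features_by_spots",
                                            "spots_by_features"),
                            row_names = NULL, col_names = NULL) {
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (fmt == "guess") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    fmt <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                  txt = "tsv",
                  stop("cannot guess format from extension '", ext,
                       "'; pass fmt=", call. = FALSE))
  }
  if (fmt == "mtx") {
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop("failed to parse Matrix Market file ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
    stem <- sub("\\.mtx(\\.gz)?$", "", path)
    if (is.null(row_names)) row_names <- paste0(stem, ".rownames.txt")
    if (is.null(col_names)) col_names <- paste0(stem, ".colnames.txt")
    rn <- if (file.exists(row_names)) readLines(row_names) else NULL
    cn <- if (file.exists(col_names)) readLines(col_names) else NULL
    if (!is.null(rn)) {
      if (length(rn) != nrow(m)) {
        stop("sidecar ", row_names, " has ", length(rn),
             " names but matrix has ", nrow(m), " rows", call. = FALSE)
      }
      rownames(m) <- rn
    }
    if (!is.null(cn)) {
      if (length(cn) != ncol(m)) {
        stop("sidecar ", col_names, " has ", length(cn),
             " names but matrix has ", ncol(m), " columns", call. = FALSE)
      }
      colnames(m) <- cn
    }
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    dt <- tryCatch(
      data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    ids <- as.character(dt[[1L]])
    body <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(body)) {
      bad <- which(!vapply(dt[-1L], is.numeric, logical(1L)))[1L] + 1L
      stop("non-numeric values in column ", bad, " of ", path, call. = FALSE)
    }
    rownames(body) <- ids
    m <- as(body, "CsparseMatrix")
  }
  if (orientation == "spots_by_features") m <- Matrix::t(m)
  if (length(m@x) && min(m@x) < 0) {
    stop("negative expression values in ", path, call. = FALSE)
  }
  expression_matrix(m)
}

#' Write an expression matrix to Matrix Market with name sidecars
#'
#' Writes `<stem>.mtx`, `<stem>.rownames.txt` (feature ids) and
#' `<stem>.colnames.txt` (spot ids).
#'
#' @param expr an [expression_matrix()].
#' @param path path to the `.mtx` file to create.
#' @return `path`, invisibly.
#' @export
write_expression_mtx <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  Matrix::writeMM(expr$values, path)
  stem <- sub("\\.mtx$", "", path)
  writeLines(expr$feature_ids, paste0(stem, ".rownames.txt"))
  cn <- colnames(expr$values)
  if (is.null(cn)) cn <- paste0("spot_", seq_len(ncol(expr$values)))
  writeLines(cn, paste0(stem, ".colnames.txt"))
  invisible(path)
}

#' Read spot coordinates from a delimited table
#'
#' @param path CSV/TSV file with a header row.
#' @param columns names of the coordinate columns, in x, y(, z) order.
#' @param id_column optional name of a spot-id column; row order is preserved
#'   either way.
#' @return a [spatial_coordinates()] with `is_rescaled = FALSE`.
#' @export
load_coordinates <- function(path, columns = intersect(c("x", "y", "z"),
                                                       names(dt)),
                             id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  columns <- force(columns)
  if (length(columns) < 2L) {
    stop("need at least two coordinate columns; found: ",
         paste(columns, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(columns, names(dt))
  if (length(missing_cols)) {
    stop("missing coordinate column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (cl in columns) {
    v <- dt[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", cl, "' at data row ",
           if (is.na(bad)) 1L else bad, call. = FALSE)
    }
  }
  pos <- as.matrix(dt[, columns, drop = FALSE])
  ids <- if (!is.null(id_column)) as.character(dt[[id_column]]) else NULL
  spatial_coordinates(pos, spot_ids = ids, is_rescaled = FALSE)
}

#' Write per-feature SVF results to CSV
#'
#' One row per input feature, in input order, with the canonical header
#' `feature_id,raw_variance,weight,ratio,p_value,excluded` (plus `q_value`
#' when BH adjustment was requested). Excluded features carry
#' `p_value = 1` and `ratio = 0`.
#'
#' @param result an `svf_result` data frame from [run_bsp()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(is.data.frame(result))
  cols <- c("feature_id", "raw_variance", "weight", "ratio", "p_value",
            "excluded")
  missing_cols <- setdiff(cols, names(result))
  if (length(missing_cols)) {
    stop("result is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if ("q_value" %in% names(result)) cols <- c(cols, "q_value")
  out <- result[, cols, drop = FALSE]
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write results to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return a data frame with the canonical result columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, data.table = FALSE)
  dt$excluded <- as.logical(dt$excluded)
  dt
}
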