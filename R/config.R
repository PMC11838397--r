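#' Run configuration for the SVF pipeline
#'
#' Bundles every tunable of [run_bsp()] into a validated record that can be
#' written to and read back from a plain `key = value` config file, so any
#' run is reproducible from its logged configuration and seed.
#'
#' @param r1,r2 small and big patch radii in rescaled units (defaults 1, 3).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param null_kind `"lognormal"` or `"permutation"`.
#' @param n_perm permutation-null size (default 1000).
#' @param neighbor_mode `"exact"` or `"approximate"`.
#' @param recall_target approximate-mode expected recall (default 0.99).
#' @param seed integer seed.
#' @param adjust `"none"` or `"bh"`.
#' @param weight_on_scaled logical; weight from scaled-matrix variances.
#' @param variance_denominator `"population"` or `"sample"`.
#' @return a `bsp_config` list.
#' @export
bsp_config <- function(r1 = 1.0, r2 = 3.0, alpha = 0.05,
                       null_kind = c("lognormal", "permutation"),
                       n_perm = 1000L,
                       neighbor_mode = c("exact", "approximate"),
                       recall_target = 0.99, seed = 1L,
                       adjust = c("none", "bh"),
                       weight_on_scaled = FALSE,
                       variance_denominator = c("population", "sample")) {
  null_kind <- match.arg(null_kind)
  neighbor_mode <- match.arg(neighbor_mode)
  adjust <- match.arg(adjust)
  variance_denominator <- match.arg(variance_denominator)
  if (!(r1 > 0 && r2 > r1)) {
    stop("config requires 0 < r1 < r2 (got r1 = ", r1, ", r2 = ", r2, ")",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(r1 = r1, r2 = r2, alpha = alpha, null_kind = null_kind,
         n_perm = as.integer(n_perm), neighbor_mode = neighbor_mode,
         recall_target = recall_target, seed = as.integer(seed),
         adjust = adjust, weight_on_scaled = isTRUE(weight_on_scaled),
         variance_denominator = variance_denominator),
    class = "bsp_config"
  )
}

#' @export
print.bsp_config <- function(x, ...) {
  cat("bsp_config:\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write a configuration to a key = value file
#'
#' @param config a [bsp_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bsp_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]], scientific = FALSE))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration from a key = value file
#'
#' Unknown keys are an error; missing keys take the [bsp_config()] defaults.
#'
#' @param path config file path.
#' @return a validated [bsp_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line: '", lines[which(bad)[1L]], "'",
         call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, `[[`, character(1L), 2L)
  known <- names(formals(bsp_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- c("r1", "r2", "alpha", "n_perm", "recall_target", "seed")
  for (k in intersect(keys, numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  if ("weight_on_scaled" %in% keys) {
    args$weight_on_scaled <- toupper(args$weight_on_scaled) %in%
      c("TRUE", "T", "1", "YES")
  }
  do.call(bsp_config, args)
}

#' Run the pipeline from a configuration record
#'
#' @param expr an [expression_matrix()].
#' @param coords a [spatial_coordinates()].
#' @param config a [bsp_config()].
#' @return the `svf_result` from [run_bsp()].
#' @export
run_bsp_config <- function(expr, coords, config = bsp_config()) {
  stopifnot(inherits(config, "bsp_config"))
  run_bsp(expr, coords, r1 = config$r1, r2 = config$r2,
          null_kind = config$null_kind, n_perm = config$n_perm,
          mode = config$neighbor_mode, recall_target = config$recall_target,
          seed = config$seed, alpha = config$alpha, adjust = config$adjust,
          weight_on_scaled = config$weight_on_scaled,
          variance_denominator = config$variance_denominator)
}
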