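#' Statistical power at realized false discovery rates
#'
#' Walks down the list of features sorted by p-value (whole tie groups taken
#' together) and records, at every prefix, the realized FDR (false
#' discoveries over discoveries, from the known labels) and the power (true
#' positives over all true SVFs). For each requested FDR level the maximum
#' power over prefixes whose realized FDR does not exceed it is reported,
#' together with the p-value threshold achieving it. Using the realized
#' (oracle) FDR rather than an estimated one makes detectors with
#' differently calibrated p-value scales comparable.
#'
#' @param p_values numeric vector of per-feature p-values.
#' @param labels per-feature truth: logical (`TRUE` = SVF) or a vector with
#'   values `"svf"`/`"null"`.
#' @param fdr_grid FDR levels to evaluate (default `seq(0, 0.3, 0.01)`).
#' @return a `power_curve` data frame with columns `fdr`, `power`,
#'   `threshold`.
#' @export
power_at_fdr <- function(p_values, labels, fdr_grid = seq(0, 0.3, 0.01)) {
  truth <- if (is.logical(labels)) labels else labels == "svf"
  if (length(truth) != length(p_values)) {
    stop("labels and p_values differ in length", call. = FALSE)
  }
  n_svf <- sum(truth); n_null <- sum(!truth)
  if (n_svf == 0L || n_null == 0L) {
    stop("labels must contain at least one SVF and one null feature",
         call. = FALSE)
  }
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  truth_sorted <- truth[ord]
  # prefix ends = last index of each p-value tie group
  ends <- which(!duplicated(p_sorted, fromLast = TRUE))
  tp <- cumsum(truth_sorted)[ends]
  n_called <- ends
  fp <- n_called - tp
  realized_fdr <- fp / n_called
  power <- tp / n_svf
  out <- data.frame(fdr = fdr_grid, power = 0, threshold = NA_real_)
  for (g in seq_along(fdr_grid)) {
    ok <- which(realized_fdr <= fdr_grid[g])
    if (length(ok)) {
      best <- ok[which.max(power[ok])]
      out$power[g] <- power[best]
      out$threshold[g] <- p_sorted[ends[best]]
    }
  }
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Jaccard index of two feature sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 0 when both sets are empty.
#'
#' @param set_a,set_b vectors of feature identifiers (duplicates ignored).
#' @return a number in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Stouffer combination of one-sided p-values across samples
#'
#' Per feature, \eqn{z_i = \Phi^{-1}(1 - p_i)} over the k samples and
#' \eqn{Z = \sum_i z_i / \sqrt{k}}, with combined p \eqn{= 1 - \Phi(Z)}.
#' Samples are unweighted (treated as exchangeable). Inputs exactly 0 or 1
#' are clipped into the open unit interval with a warning, since
#' \eqn{\Phi^{-1}} diverges there.
#'
#' @param p_matrix numeric matrix (features x samples, k >= 2 columns) or a
#'   list/data frame of equal-length p-value vectors, aligned by feature.
#' @param feature_ids optional feature identifiers (default row names or
#'   `feature_1 ...`).
#' @return a `meta_result` data frame with columns `feature_id`, `z`,
#'   `p_combined`; the per-sample inputs are kept in attribute `samples`.
#' @export
stouffer_combine <- function(p_matrix, feature_ids = NULL) {
  if (is.list(p_matrix) && !is.data.frame(p_matrix)) {
    p_matrix <- do.call(cbind, p_matrix)
  }
  p_matrix <- as.matrix(p_matrix)
  k <- ncol(p_matrix)
  if (k < 2L) stop("need p-values from at least 2 samples", call. = FALSE)
  if (any(!is.finite(p_matrix)) || any(p_matrix < 0) || any(p_matrix > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  at_edge <- p_matrix <= 0 | p_matrix >= 1
  if (any(at_edge)) {
    warning(sum(at_edge), " p-value(s) at 0 or 1 clipped into (0, 1) ",
            "before the normal-quantile transform")
    p_matrix <- pmin(pmax(p_matrix, .Machine$double.xmin),
                     1 - .Machine$double.eps / 2)
  }
  z <- qnorm(p_matrix, lower.tail = FALSE)
  Z <- rowSums(z) / sqrt(k)
  p_comb <- pmax(pnorm(Z, lower.tail = FALSE), .Machine$double.xmin)
  if (is.null(feature_ids)) {
    feature_ids <- rownames(p_matrix)
    if (is.null(feature_ids)) {
      feature_ids <- paste0("feature_", seq_len(nrow(p_matrix)))
    }
  }
  out <- data.frame(feature_id = feature_ids, z = Z, p_combined = p_comb,
                    stringsAsFactors = FALSE)
  attr(out, "samples") <- p_matrix
  class(out) <- c("meta_result", "data.frame")
  out
}
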