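#' Pearson correlation matrix of a feature table
#'
#' Pairwise-complete Pearson correlations between all feature columns
#' (categorical covariates contribute their integer codes). Constant
#' features, or pairs with fewer than two complete observations, yield
#' `NA` entries rather than errors.
#'
#' @param table a [feature_table()].
#' @return A symmetric numeric matrix with unit diagonal (where defined).
#' @export
pearson_correlation_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  suppressWarnings(stats::cor(table$values, use = "pairwise.complete.obs"))
}

#' Find correlated feature pairs
#'
#' Lists all unordered feature pairs whose absolute correlation strictly
#' exceeds the threshold, sorted by `|r|` descending, ties broken
#' lexicographically by feature names. `NA` entries never form pairs.
#'
#' @param matrix symmetric correlation matrix with dimnames.
#' @param threshold strict lower bound on `|r|` (default 0.5).
#' @return A `data.frame` with columns `feature_a`, `feature_b`, `r`.
#' @export
find_correlated_pairs <- function(matrix, threshold = 0.5) {
  nm <- colnames(matrix)
  ij <- which(upper.tri(matrix) & !is.na(matrix) & abs(matrix) > threshold,
              arr.ind = TRUE)
  out <- data.frame(feature_a = nm[ij[, 1]], feature_b = nm[ij[, 2]],
                    r = matrix[ij], stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$feature_a, out$feature_b), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Mutual information between a feature and the class label
#'
#' Plug-in estimate of \eqn{I(X;Y) = H(X) - H(X|Y)} in nats. Continuous
#' features are discretized by equal-frequency binning into at most
#' `n_bins` bins; features with no more distinct values than `n_bins` are
#' used as discrete categories directly, in which case the estimate equals
#' the exact plug-in double sum over the joint table. Missing feature
#' values are dropped; the result is clamped at zero.
#'
#' @param x numeric feature values.
#' @param y class labels (any vector coercible to factor).
#' @param n_bins maximum number of bins for continuous features (>= 2).
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  keep <- !is.na(x)
  if (!any(keep)) stop("all feature values missing", call. = FALSE)
  x <- x[keep]; y <- y[keep]
  ux <- unique(x)
  if (length(ux) > n_bins) {
    if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE))
    if (length(br) < 2L) br <- range(x) + c(-1, 1)
    x <- cut(x, breaks = br, include.lowest = TRUE)
  }
  joint <- table(x, y)
  pxy <- joint / sum(joint)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' Redundancy-removing feature reduction
#'
#' Two-step reduction: correlated feature pairs (`|r| >` threshold on the
#' training data) are found, then within each pair the member with the
#' lower mutual information with the class label is dropped. Pairs are
#' processed in `|r|`-descending order and a pair is skipped when either
#' member was already dropped, so at most one member of each pair is ever
#' removed. MI ties keep the feature earlier in column order.
#'
#' @param table a [feature_table()] (the training split).
#' @param threshold strict `|r|` threshold (default 0.5).
#' @param n_bins bins for [mutual_information()] (default 10).
#' @return An object of class `"reduction_report"`: `threshold`, `pairs`
#'   (a `data.frame` with the per-pair MI values and the dropped member),
#'   `kept_features`, `dropped_features`.
#' @export
reduce_features <- function(table, threshold = 0.5, n_bins = 10) {
  stopifnot(inherits(table, "feature_table"))
  cm <- pearson_correlation_matrix(table)
  pairs <- find_correlated_pairs(cm, threshold)
  feats <- colnames(table$values)
  mi_cache <- new.env(parent = emptyenv())
  mi_of <- function(f) {
    if (is.null(mi_cache[[f]])) {
      mi_cache[[f]] <- mutual_information(table$values[, f], table$labels,
                                          n_bins)
    }
    mi_cache[[f]]
  }
  dropped <- character(0)
  rec <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$feature_a[i]; b <- pairs$feature_b[i]
    if (a %in% dropped || b %in% dropped) next
    mi_a <- mi_of(a); mi_b <- mi_of(b)
    drop <- if (mi_a < mi_b) a
            else if (mi_b < mi_a) b
            else feats[max(match(c(a, b), feats))]  # tie: keep earlier column
    dropped <- c(dropped, drop)
    rec[[length(rec) + 1L]] <- data.frame(
      feature_a = a, feature_b = b, r = pairs$r[i], mi_a = mi_a, mi_b = mi_b,
      dropped = drop, stringsAsFactors = FALSE)
  }
  structure(list(
    threshold = threshold,
    pairs = if (length(rec)) do.call(rbind, rec) else
      data.frame(feature_a = character(0), feature_b = character(0),
                 r = numeric(0), mi_a = numeric(0), mi_b = numeric(0),
                 dropped = character(0)),
    kept_features = setdiff(feats, dropped),
    dropped_features = dropped),
    class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("<reduction_report> |r| >", x$threshold, "\n")
  cat("  kept:   ", length(x$kept_features), "features\n")
  cat("  dropped:", if (length(x$dropped_features))
        paste(x$dropped_features, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
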