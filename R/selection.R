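#' One gain-importance ranking round
#'
#' Fits a gradient-boosted tree classifier on the given feature subset
#' (binary log-loss objective, misclassification error rate monitored) and
#' ranks the features by gain importance — the share of total split gain
#' each feature contributes. Zero-importance features rank below all
#' positive-gain features; ties keep column order.
#'
#' @param train a binary-labelled [feature_table()].
#' @param features feature names to use (subset of the table's columns).
#' @param top_k number of top features to report (default 10).
#' @param positive the positive class label.
#' @param learner list of learner settings (`n_estimators`, `num_leaves`,
#'   `learning_rate`).
#' @param seed integer seed for the learner.
#' @return A list of class `"selection_round"` with `input_features`,
#'   `importances` (named, sorted), and `top_features`.
#' @export
importance_round <- function(train, features, top_k = 10,
                             positive = train$class_set[1],
                             learner = list(), seed = 0L) {
  stopifnot(inherits(train, "feature_table"))
  features <- intersect(colnames(train$values), features)  # canonical order
  y <- binary_target(train$labels, positive)
  model <- boost_fit(train$values[, features, drop = FALSE], y,
                     params = learner, seed = seed)
  gains <- boost_gain_importance(model)
  ord <- order(-gains, match(names(gains), features))
  gains <- gains[ord]
  structure(list(input_features = features,
                 importances = gains,
                 top_features = names(gains)[seq_len(min(top_k,
                                                         length(gains)))]),
            class = "selection_round")
}

#' Iterative gain-importance feature selection
#'
#' Runs `n_rounds` ranking rounds on progressively smaller feature sets:
#' round 1 uses all features; between rounds the `floor(n / n_rounds)`
#' lowest-gain features are removed, so with 40 features and 5 rounds the
#' round sizes are 40, 32, 24, 16, 8. Each round's top `top_k` features
#' are recorded and the final selection is their union in first-occurrence
#' order, deduplicated.
#'
#' @inheritParams importance_round
#' @param n_rounds number of rounds (default 5).
#' @return An object of class `"selection_report"`: `subset_size`,
#'   `rounds` (list of [importance_round()] results), and `selected`.
#' @export
select_features <- function(train, n_rounds = 5, top_k = 10,
                            positive = train$class_set[1],
                            learner = list(), seed = 0L) {
  stopifnot(inherits(train, "feature_table"))
  if (n_rounds < 1) stop("config error: n_rounds must be >= 1", call. = FALSE)
  feats <- colnames(train$values)
  if (length(feats) < n_rounds) {
    stop("fewer features than rounds", call. = FALSE)
  }
  subset_size <- floor(length(feats) / n_rounds)
  rounds <- vector("list", n_rounds)
  current <- feats
  for (t in seq_len(n_rounds)) {
    rounds[[t]] <- importance_round(train, current, top_k = top_k,
                                    positive = positive, learner = learner,
                                    seed = seed)
    if (t < n_rounds) {
      ranked <- names(rounds[[t]]$importances)  # gain-descending
      current <- intersect(feats,                # keep canonical order
                           ranked[seq_len(length(ranked) - subset_size)])
    }
  }
  selected <- unique(unlist(lapply(rounds, `[[`, "top_features")))
  structure(list(subset_size = subset_size, rounds = rounds,
                 selected = selected),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  sizes <- vapply(x$rounds, function(r) length(r$input_features), integer(1))
  cat("<selection_report> ", length(x$rounds), " rounds, sizes ",
      paste(sizes, collapse = "/"), "\n", sep = "")
  cat("  selected (", length(x$selected), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}
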