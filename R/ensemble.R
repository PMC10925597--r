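#' Hyperparameter search space
#'
#' Candidate grids for the boosted-tree classifier's random search. The
#' defaults are the published grids: `n_estimators` in 50, 100, ..., 500;
#' `num_leaves` over a 50-point grid from 5 to 500; `learning_rate`
#' continuous uniform on (0, 1).
#'
#' @param n_estimators candidate tree counts.
#' @param num_leaves candidate leaf counts.
#' @param n_iterations number of random configurations to score.
#' @return A list of class `"search_space"`.
#' @export
search_space <- function(n_estimators = seq(50L, 500L, by = 50L),
                         num_leaves = default_num_leaves_grid(),
                         n_iterations = 60L) {
  if (!length(n_estimators) || !length(num_leaves)) {
    stop("config error: empty candidate list", call. = FALSE)
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 num_leaves = as.integer(num_leaves),
                 n_iterations = as.integer(n_iterations)),
            class = "search_space")
}

default_num_leaves_grid <- function() {
  c(5L, 15L, 25L, 35L, 45L, 55L, 65L, 75L, 85L, 95L, 106L, 116L, 126L, 136L,
    146L, 156L, 166L, 176L, 186L, 196L, 207L, 217L, 227L, 237L, 247L, 257L,
    267L, 277L, 287L, 297L, 308L, 318L, 328L, 338L, 348L, 358L, 368L, 378L,
    388L, 398L, 409L, 419L, 429L, 439L, 449L, 459L, 469L, 479L, 489L, 500L)
}

#' Random-search hyperparameter tuning
#'
#' Samples `n_iterations` configurations from the space (learning rate
#' uniform on (0, 1)) and scores each by mean balanced accuracy over an
#' inner stratified k-fold cross-validation on the training set. Returns
#' the best configuration; ties go to the first sampled.
#'
#' @param train a binary-labelled [feature_table()].
#' @param space a [search_space()].
#' @param positive positive class label.
#' @param k_inner inner CV folds (default 5).
#' @param seed integer seed governing both sampling and fold assignment.
#' @return A list with `params` (`n_estimators`, `num_leaves`,
#'   `learning_rate`), `score` (mean balanced accuracy), and the per-trial
#'   `trials` data frame.
#' @export
random_search <- function(train, space = search_space(),
                          positive = train$class_set[1],
                          k_inner = 5, seed = 0L) {
  stopifnot(inherits(train, "feature_table"), inherits(space, "search_space"))
  y <- binary_target(train$labels, positive)
  if (min(table(y)) < 2) stop("need >= 2 samples per class", call. = FALSE)
  x <- train$values
  with_seed(seed, {
    pick <- function(grid) {
      grid[sample.int(length(grid), space$n_iterations, replace = TRUE)]
    }
    cand <- data.frame(
      n_estimators = pick(space$n_estimators),
      num_leaves = pick(space$num_leaves),
      learning_rate = stats::runif(space$n_iterations))
    folds <- stratified_folds(train$labels, k_inner)
    scores <- vapply(seq_len(space$n_iterations), function(i) {
      params <- as.list(cand[i, ])
      bal <- vapply(seq_len(k_inner), function(f) {
        tr <- folds != f
        m <- boost_fit(x[tr, , drop = FALSE], y[tr], params, seed = seed)
        p <- boost_predict(m, x[!tr, , drop = FALSE])
        cm <- confusion_matrix(y[!tr], as.integer(p >= 0.5))
        compute_metrics(cm)$balanced_accuracy
      }, numeric(1))
      mean(bal, na.rm = TRUE)
    }, numeric(1))
  })
  best <- which.max(scores)  # first maximum on ties
  list(params = as.list(cand[best, ]), score = scores[best],
       trials = cbind(cand, score = scores))
}

#' Cross-validation ensemble of boosted-tree classifiers
#'
#' Trains k fold models (each on k-1 folds of a stratified partition),
#' records each model's balanced accuracy on its held-out fold, and bundles
#' them into a soft-voting ensemble whose weights are those balanced
#' accuracies. The reported summary is the mean of the k fold balanced
#' accuracies.
#'
#' @param train a binary-labelled [feature_table()].
#' @param params learner settings (`n_estimators`, `num_leaves`,
#'   `learning_rate`), e.g. the `params` element of [random_search()].
#' @param k number of folds (default 10).
#' @param positive positive class label.
#' @param seed integer seed for fold assignment.
#' @param threshold decision threshold on the ensemble score (default 0.5).
#' @return An object of class `"cancer_ensemble"`.
#' @export
fit_ensemble <- function(train, params = list(), k = 10,
                         positive = train$class_set[1], seed = 0L,
                         threshold = 0.5) {
  stopifnot(inherits(train, "feature_table"))
  y <- binary_target(train$labels, positive)
  folds <- with_seed(seed, stratified_folds(train$labels, k))
  x <- train$values
  fold_models <- vector("list", k)
  bal <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_models[[f]] <- boost_fit(x[tr, , drop = FALSE], y[tr], params,
                                  seed = seed)
    p <- boost_predict(fold_models[[f]], x[!tr, , drop = FALSE])
    cm <- confusion_matrix(y[!tr], as.integer(p >= 0.5))
    bal[f] <- compute_metrics(cm)$balanced_accuracy
  }
  structure(list(fold_models = fold_models,
                 fold_balanced_accuracies = bal,
                 params = utils::modifyList(boost_defaults(), params),
                 feature_names = colnames(x),
                 positive = positive, threshold = threshold, seed = seed),
            class = "cancer_ensemble")
}

#' @export
print.cancer_ensemble <- function(x, ...) {
  cat("<cancer_ensemble> ", length(x$fold_models),
      " fold models, positive class '", x$positive, "'\n", sep = "")
  cat(sprintf("  mean fold balanced accuracy: %.4f\n",
              mean(x$fold_balanced_accuracies)))
  cat("  params: n_estimators=", x$params$n_estimators, ", num_leaves=",
      x$params$num_leaves, ", learning_rate=",
      signif(x$params$learning_rate, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cancer_ensemble <- function(object, ...) {
  cat("Cross-validation ensemble (", length(object$fold_models),
      " folds)\n", sep = "")
  print(object)
  cat("  fold balanced accuracies:",
      paste(sprintf("%.3f", object$fold_balanced_accuracies),
            collapse = " "), "\n")
  invisible(object)
}

#' Predict from a cross-validation ensemble
#'
#' Soft voting: the ensemble score is the balanced-accuracy-weighted mean
#' of the fold models' positive-class probabilities (weights normalized by
#' their sum), and the label is positive when the score reaches the
#' threshold (half-up at the boundary).
#'
#' @param object a [fit_ensemble()] model.
#' @param newdata a [feature_table()] or numeric matrix containing the
#'   model's features.
#' @param type `"score"` for the weighted probability, `"label"` for the
#'   thresholded class, `"both"` for a list with both.
#' @param ... unused.
#' @return Per `type`: numeric scores in `[0, 1]`, integer 0/1 labels, or
#'   a list `list(scores=, labels=)`.
#' @export
predict.cancer_ensemble <- function(object, newdata, type = "both", ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$values else newdata
  miss <- setdiff(object$feature_names, colnames(x))
  if (length(miss)) {
    stop("schema error: missing features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, object$feature_names, drop = FALSE]
  w <- object$fold_balanced_accuracies
  probs <- vapply(object$fold_models, boost_predict, numeric(nrow(x)), x = x)
  probs <- matrix(probs, nrow = nrow(x))
  scores <- as.numeric(probs %*% w) / sum(w)
  labels <- as.integer(scores >= object$threshold)
  switch(type,
         score = scores,
         label = labels,
         both = list(scores = scores, labels = labels))
}
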