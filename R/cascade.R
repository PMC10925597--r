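#' Build the cascade's per-stage binary datasets
#'
#' Stage 0 is the full cohort relabelled Cancer/Normal (detection). Stage
#' t (t >= 1) keeps only the cancer types from position t-1 onward in
#' `class_order` and labels them `class_order[t-1]` versus `"other"`, so a
#' 7-type cohort yields 7 binary datasets of strictly decreasing size
#' after the detection stage.
#'
#' @param table a [feature_table()] whose labels are `"Normal"` plus
#'   cancer types.
#' @param class_order character vector ordering the cancer types.
#' @return A list of binary-labelled feature tables; element 1 is the
#'   detection dataset.
#' @export
build_stage_datasets <- function(table, class_order) {
  stopifnot(inherits(table, "feature_table"))
  if (length(class_order) < 2) stop("need >= 2 cancer types", call. = FALSE)
  extra <- setdiff(table$class_set, c("Normal", class_order))
  if (length(extra)) {
    stop("labels outside Normal + class_order: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing_cls <- setdiff(class_order, table$class_set)
  if (length(missing_cls)) {
    stop("cancer type with zero samples: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  detection <- group_labels(
    table, stats::setNames(rep("Cancer", length(class_order)), class_order))
  out <- list(detection)
  for (t in seq_len(length(class_order) - 1L)) {
    keep_classes <- class_order[t:length(class_order)]
    rows <- which(table$labels %in% keep_classes)
    sub <- subset_table(table, rows)
    lab <- ifelse(sub$labels == class_order[t], class_order[t], "other")
    out[[t + 1L]] <- feature_table(sub$values, lab, sub$meta,
                                   sub$sample_ids, sub$codes)
  }
  out
}

#' Fit the multi-level cancer classification cascade
#'
#' Runs the full pipeline independently for every stage dataset from
#' [build_stage_datasets()]: stratified train/test split, correlation +
#' mutual-information feature reduction, iterative gain-importance feature
#' selection, random-search hyperparameter tuning, k-fold
#' cross-validation ensembling, and evaluation on the stage's held-out
#' test split. Stage s uses derived seed `seed + s`, so stages are
#' independently reproducible.
#'
#' @param table cohort [feature_table()] labelled `"Normal"` + cancer
#'   types.
#' @param class_order order in which the cascade claims cancer types;
#'   default is the cohort's cancer types in first-appearance order.
#' @param test_fraction held-out fraction per stage (default 0.1).
#' @param cor_threshold correlation threshold for [reduce_features()].
#' @param n_bins MI bins for [reduce_features()].
#' @param n_rounds,top_k selection parameters for [select_features()].
#' @param space a [search_space()] for [random_search()].
#' @param k cross-validation folds for [fit_ensemble()] (default 10).
#' @param seed integer master seed.
#' @return An object of class `"cancer_cascade"`: a list of stages, each
#'   carrying its `positive` label, `reduction`, `selection`, tuning
#'   result, `ensemble` and `test_metrics`.
#' @export
fit_cascade <- function(table, class_order = NULL, test_fraction = 0.1,
                        cor_threshold = 0.5, n_bins = 10, n_rounds = 5,
                        top_k = 10, space = search_space(), k = 10,
                        seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  class_order <- class_order %||% setdiff(table$class_set, "Normal")
  datasets <- if (length(class_order) >= 2) {
    build_stage_datasets(table, class_order)
  } else {
    list(group_labels(table, stats::setNames("Cancer", class_order)))
  }
  stages <- vector("list", length(datasets))
  for (s in seq_along(datasets)) {
    ds <- datasets[[s]]
    positive <- if (s == 1L) "Cancer" else class_order[s - 1L]
    stage_seed <- seed + s - 1L
    split <- stratified_split(ds, test_fraction, stage_seed)
    red <- reduce_features(split$train, cor_threshold, n_bins)
    train_red <- subset_table(split$train, cols = red$kept_features)
    sel <- select_features(train_red, n_rounds = n_rounds, top_k = top_k,
                           positive = positive, seed = stage_seed)
    train_sel <- subset_table(split$train, cols = sel$selected)
    tune <- random_search(train_sel, space, positive = positive,
                          seed = stage_seed)
    ens <- fit_ensemble(train_sel, tune$params, k = k, positive = positive,
                        seed = stage_seed)
    pred <- predict(ens, split$test)
    y <- binary_target(split$test$labels, positive)
    metrics <- compute_metrics(confusion_matrix(y, pred$labels),
                               auc = roc_auc(y, pred$scores))
    stages[[s]] <- list(stage_index = s - 1L, positive = positive,
                        n_samples = nrow(ds$values), split = NULL,
                        reduction = red, selection = sel, tuning = tune,
                        ensemble = ens, test_metrics = metrics,
                        seed = stage_seed)
  }
  structure(list(stages = stages, class_order = class_order, seed = seed),
            class = "cancer_cascade")
}

#' @export
print.cancer_cascade <- function(x, ...) {
  cat("<cancer_cascade> ", length(x$stages), " stages; type order: ",
      paste(x$class_order, collapse = " > "), "\n", sep = "")
  for (s in x$stages) {
    cat(sprintf("  stage %d [%s]: %d features, test bal.acc %.3f\n",
                s$stage_index, s$positive, length(s$selection$selected),
                s$test_metrics$balanced_accuracy))
  }
  invisible(x)
}

#' @export
summary.cancer_cascade <- function(object, ...) {
  print(object)
  avg <- stage_macro_average(lapply(object$stages, `[[`, "test_metrics"))
  cat("macro-average over stages:\n")
  print(avg)
  invisible(object)
}

#' Predict cancer status and type with a fitted cascade
#'
#' Each sample first passes the detection stage; a negative verdict ends
#' with `"Normal"`. Otherwise the typing stages are walked in order and
#' the first stage whose ensemble votes positive assigns its cancer type;
#' a sample rejected by every typing stage receives the last type in
#' `class_order`, making the decision total.
#'
#' @param object a [fit_cascade()] model.
#' @param newdata a [feature_table()] (or matrix) with every stage's
#'   features.
#' @param ... unused.
#' @return Character vector of labels in `{"Normal"} + class_order`.
#' @export
predict.cancer_cascade <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$values else newdata
  n <- nrow(x)
  out <- rep(NA_character_, n)
  det <- predict(object$stages[[1]]$ensemble, x)
  out[det$labels == 0L] <- "Normal"
  active <- det$labels == 1L
  if (length(object$stages) > 1L) {
    for (s in 2:length(object$stages)) {
      if (!any(active)) break
      st <- object$stages[[s]]
      pred <- predict(st$ensemble, x[active, , drop = FALSE])
      hit <- pred$labels == 1L
      idx <- which(active)
      out[idx[hit]] <- st$positive
      active[idx[hit]] <- FALSE
    }
  }
  out[is.na(out)] <- object$class_order[length(object$class_order)]
  out
}
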