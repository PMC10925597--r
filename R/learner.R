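# Gradient-boosted tree learner contract: fit / predict-probability /
# per-feature gain importance. Backed by xgboost's histogram algorithm with
# leaf-wise (lossguide) growth, the same tree-growing strategy as LightGBM.
# Single-threaded by default so fits are bit-reproducible.

boost_defaults <- function() {
  list(n_estimators = 100L, num_leaves = 31L, learning_rate = 0.1,
       nthread = 1L)
}

boost_fit <- function(x, y, params = list(), seed = 0L) {
  params <- utils::modifyList(boost_defaults(), params)
  if (length(unique(y)) < 2L) {
    stop("single-class target: cannot fit a binary classifier", call. = FALSE)
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = params$nthread)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "error",
                  tree_method = "hist", grow_policy = "lossguide",
                  max_depth = 0L, max_leaves = params$num_leaves,
                  eta = params$learning_rate, nthread = params$nthread,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = params$n_estimators, verbose = 0)
  structure(list(booster = bst, feature_names = colnames(x), params = params),
            class = "boost_model")
}

boost_predict <- function(model, x) {
  x <- x[, model$feature_names, drop = FALSE]
  stats::predict(model$booster,
                 xgboost::xgb.DMatrix(x, nthread = model$params$nthread))
}

# Gain share per feature (total split gain normalized to sum 1); features
# never used in a split get 0.
boost_gain_importance <- function(model) {
  gains <- stats::setNames(numeric(length(model$feature_names)),
                           model$feature_names)
  imp <- tryCatch(xgboost::xgb.importance(model = model$booster),
                  error = function(e) NULL)
  if (!is.null(imp) && nrow(imp)) {
    gains[imp$Feature] <- imp$Gain
    return(gains)
  }
  # xgb.importance chokes on single-feature boosters; aggregate split gain
  # from the dumped trees instead
  tree <- tryCatch(xgboost::xgb.model.dt.tree(model = model$booster),
                   error = function(e) NULL)
  if (!is.null(tree)) {
    splits <- tree[tree$Feature != "Leaf", , drop = FALSE]
    if (nrow(splits)) {
      agg <- tapply(splits$Gain, splits$Feature, sum)
      agg <- agg / sum(agg)
      gains[names(agg)] <- as.numeric(agg)
    }
  }
  gains
}

# 0/1 encoding of a binary label vector against a declared positive class.
binary_target <- function(labels, positive) {
  if (!positive %in% labels) {
    stop("positive class '", positive, "' absent from labels", call. = FALSE)
  }
  as.integer(labels == positive)
}
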