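#' Run the full detection (and optionally typing) pipeline
#'
#' End-to-end orchestration: obtain a cohort (synthetic or from file),
#' collapse labels to Cancer/Normal, stratified-split, reduce, select,
#' tune, train the cross-validation ensemble, and evaluate on the held-out
#' test split; optionally fit the full typing cascade as well. All reports
#' are written as JSON under `out_dir`; a rerun with the same config and
#' seed reproduces the JSON reports byte-identically.
#'
#' @param config a list (or path to a JSON file) with entries:
#'   `seed` (mandatory); either `input` + `schema` (paths for
#'   [load_feature_table()]) or `synthetic` (arguments for
#'   [cohort_config()], or `TRUE` for the defaults); `out_dir`;
#'   `test_fraction` (0.1), `cor_threshold` (0.5), `n_bins` (10),
#'   `n_rounds` (5), `top_k` (10), `k_folds` (10), `n_iterations` (60),
#'   `cascade` (logical, default `FALSE`), `class_order` (optional).
#' @param out_dir output directory; overrides `config$out_dir`. The
#'   directory is not part of the serialized config, so the same config
#'   and seed give byte-identical reports wherever they are written.
#' @return Invisibly, a list with the fitted objects and report paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config error: seed is mandatory",
                                 call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- out_dir %||% config$out_dir %||% "pipeline_run"
  config$out_dir <- NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  wjson <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    p
  }

  logf("loading cohort")
  cohort <- if (!is.null(config$input)) {
    load_feature_table(config$input, config$schema,
                       sep = config$sep %||% ",")
  } else {
    syn <- config$synthetic
    cc <- if (is.list(syn)) do.call(cohort_config, c(syn, list(seed = seed)))
          else cohort_config(seed = seed)
    generate_cohort(cc)
  }
  cancer_types <- setdiff(cohort$class_set, "Normal")
  detection <- group_labels(
    cohort, stats::setNames(rep("Cancer", length(cancer_types)),
                            cancer_types))

  tf <- config$test_fraction %||% 0.1
  space <- search_space(n_iterations = config$n_iterations %||% 60L)
  logf("detection: split/reduce/select/tune/train")
  split <- stratified_split(detection, tf, seed)
  red <- reduce_features(split$train, config$cor_threshold %||% 0.5,
                         config$n_bins %||% 10)
  train_red <- subset_table(split$train, cols = red$kept_features)
  sel <- select_features(train_red, n_rounds = config$n_rounds %||% 5,
                         top_k = config$top_k %||% 10,
                         positive = "Cancer", seed = seed)
  train_sel <- subset_table(split$train, cols = sel$selected)
  tune <- random_search(train_sel, space, positive = "Cancer", seed = seed)
  ens <- fit_ensemble(train_sel, tune$params, k = config$k_folds %||% 10,
                      positive = "Cancer", seed = seed)
  pred <- predict(ens, split$test)
  y <- binary_target(split$test$labels, "Cancer")
  metrics <- compute_metrics(confusion_matrix(y, pred$labels),
                             auc = roc_auc(y, pred$scores))
  panel <- cohort$meta[match(sel$selected, cohort$meta$name), , drop = FALSE]
  panel <- panel[!is.na(panel$name), , drop = FALSE]
  cost <- panel_cost(panel)

  paths <- c(
    config = wjson(config, "config.json"),
    reduction = wjson(reduction_report_json(red), "reduction.json"),
    selection = wjson(selection_report_json(sel), "selection.json"),
    params = wjson(c(tune$params, inner_cv_score = tune$score),
                   "params.json"),
    detection_metrics = wjson(unclass(metrics), "detection_metrics.json"),
    cost = wjson(cost, "cost.json"))

  cascade <- NULL
  if (isTRUE(config$cascade) && length(cancer_types) >= 2) {
    logf("fitting typing cascade")
    cascade <- fit_cascade(
      cohort, class_order = config$class_order %||% cancer_types,
      test_fraction = tf, cor_threshold = config$cor_threshold %||% 0.5,
      n_bins = config$n_bins %||% 10, n_rounds = config$n_rounds %||% 5,
      top_k = config$top_k %||% 10, space = space,
      k = config$k_folds %||% 10, seed = seed)
    per_stage <- lapply(cascade$stages, function(s)
      c(list(stage = s$stage_index, positive = s$positive),
        unclass(s$test_metrics)))
    macro <- stage_macro_average(lapply(cascade$stages, `[[`,
                                        "test_metrics"))
    paths <- c(paths, cascade_metrics = wjson(
      list(stages = per_stage, macro_average = unclass(macro)),
      "cascade_metrics.json"))
  }

  manifest <- list(
    package = "liquidcascade",
    version = as.character(utils::packageVersion("liquidcascade")),
    seed = seed,
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.json"))))
  paths <- c(paths, manifest = wjson(manifest, "manifest.json"))
  logf("done")
  invisible(list(cohort = cohort, split = split, reduction = red,
                 selection = sel, tuning = tune, ensemble = ens,
                 test_metrics = metrics, cost = cost, cascade = cascade,
                 paths = paths, out_dir = out_dir))
}

reduction_report_json <- function(red) {
  list(threshold = red$threshold, pairs = red$pairs,
       kept_features = red$kept_features,
       dropped_features = red$dropped_features,
       n_kept = length(red$kept_features),
       n_dropped = length(red$dropped_features))
}

selection_report_json <- function(sel) {
  list(subset_size = sel$subset_size,
       rounds = lapply(sel$rounds, function(r)
         list(n_input = length(r$input_features),
              importances = as.list(r$importances),
              top_features = r$top_features)),
       selected = sel$selected, n_selected = length(sel$selected))
}
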