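#' Per-feature metadata for a cohort table
#'
#' Builds the metadata frame describing each column of a [feature_table()]:
#' the feature kind (plasma protein biomarker, clinical covariate, or the
#' cfDNA omega score) and, for biomarkers, whether the assay is one of the
#' six in routine clinical use (AFP, CA 19-9, CA 125, CEA, Prolactin,
#' CA 15-3) — the routine flag drives the assay cost model.
#'
#' @param name character vector of unique feature names.
#' @param kind one of `"biomarker"`, `"clinical"`, `"omega"` per feature.
#' @param routine logical; `TRUE` only allowed for biomarkers.
#' @param unit free-text unit (e.g. `"pg/ml"`); empty string if unknown.
#' @return A `data.frame` with columns `name`, `kind`, `routine`, `unit`.
#' @export
feature_meta <- function(name, kind = "biomarker", routine = FALSE, unit = "") {
  n <- length(name)
  kind <- rep_len(as.character(kind), n)
  routine <- rep_len(as.logical(routine), n)
  unit <- rep_len(as.character(unit), n)
  bad <- setdiff(unique(kind), c("biomarker", "clinical", "omega"))
  if (length(bad)) {
    stop("unknown feature kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("validation error: duplicate feature names", call. = FALSE)
  }
  if (any(routine & kind != "biomarker")) {
    stop("validation error: routine = TRUE requires kind = 'biomarker'",
         call. = FALSE)
  }
  data.frame(name = as.character(name), kind = kind, routine = routine,
             unit = unit, stringsAsFactors = FALSE)
}

#' Cohort feature table
#'
#' The universal currency of the pipeline: a samples-by-features numeric
#' matrix with per-feature metadata and a class label per sample. Biomarker
#' concentrations are non-negative; missing values are carried as `NA` and
#' passed through to learners that handle them natively (no imputation).
#' Categorical clinical covariates (sex, race) are stored as small
#' non-negative integer codes with the level table kept in `codes`, so a
#' covariate stays a single feature column.
#'
#' @param values numeric matrix, one row per sample, one column per feature;
#'   column names must match `meta$name`.
#' @param labels character vector of class labels, one per sample.
#' @param meta metadata frame from [feature_meta()]; defaults to treating
#'   every column as a biomarker.
#' @param sample_ids optional character ids; defaults to `s1, s2, ...`.
#' @param codes named list mapping categorical feature name to its ordered
#'   level vector (code `i-1` = level `i`).
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(values, labels, meta = NULL, sample_ids = NULL,
                          codes = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(meta)) {
    if (is.null(colnames(values))) {
      colnames(values) <- paste0("f", seq_len(ncol(values)))
    }
    meta <- feature_meta(colnames(values))
  }
  if (is.null(colnames(values))) colnames(values) <- meta$name
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  x <- structure(
    list(values = values, labels = as.character(labels), meta = meta,
         sample_ids = as.character(sample_ids),
         class_set = unique(as.character(labels)), codes = codes),
    class = "feature_table")
  validate_feature_table(x)
}

validate_feature_table <- function(x) {
  if (nrow(x$values) == 0L) {
    stop("validation error: empty table", call. = FALSE)
  }
  if (nrow(x$values) != length(x$labels) ||
      nrow(x$values) != length(x$sample_ids)) {
    stop("validation error: rows, labels and sample_ids disagree",
         call. = FALSE)
  }
  if (ncol(x$values) != nrow(x$meta) ||
      !identical(colnames(x$values), x$meta$name)) {
    stop("validation error: value columns do not match metadata",
         call. = FALSE)
  }
  if (anyDuplicated(x$meta$name)) {
    stop("validation error: duplicate feature names", call. = FALSE)
  }
  if (!all(x$labels %in% x$class_set)) {
    stop("validation error: label outside class_set", call. = FALSE)
  }
  bio <- x$meta$kind == "biomarker"
  if (any(bio)) {
    v <- x$values[, bio, drop = FALSE]
    if (any(v < 0, na.rm = TRUE)) {
      stop("validation error: negative biomarker concentration", call. = FALSE)
    }
  }
  x
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  cat("  kinds:  ", paste(sprintf("%s=%d", names(table(x$meta$kind)),
                                  table(x$meta$kind)), collapse = ", "), "\n")
  cts <- table(factor(x$labels, levels = x$class_set))
  cat("  classes:", paste(sprintf("%s=%d", names(cts), cts), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table
#'
#' Row/column subset that keeps the object valid: metadata, labels, sample
#' ids and categorical code tables follow the selection.
#'
#' @param x a [feature_table()].
#' @param rows row indices (default all).
#' @param cols feature names or column indices (default all).
#' @return A [feature_table()].
#' @export
subset_table <- function(x, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(x$values))
  cols <- cols %||% colnames(x$values)
  if (is.character(cols)) {
    miss <- setdiff(cols, colnames(x$values))
    if (length(miss)) {
      stop("schema error: unknown features: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  v <- x$values[rows, cols, drop = FALSE]
  m <- x$meta[match(colnames(v), x$meta$name), , drop = FALSE]
  rownames(m) <- NULL
  feature_table(v, x$labels[rows], m, x$sample_ids[rows],
                codes = x$codes[intersect(names(x$codes), colnames(v))])
}

#' Regroup class labels
#'
#' Applies a label mapping, e.g. merging esophageal and gastric cancers
#' into a single "Upper GI" class, or collapsing every cancer type to
#' "Cancer" for the detection stage.
#'
#' @param table a [feature_table()].
#' @param mapping named character vector `old label -> new label`; labels
#'   not named are left unchanged.
#' @return A [feature_table()] with recomputed `class_set`; sample count
#'   unchanged.
#' @export
group_labels <- function(table, mapping) {
  stopifnot(inherits(table, "feature_table"))
  mapping <- unlist(mapping)
  extra <- setdiff(names(mapping), table$class_set)
  if (length(extra)) {
    stop("validation error: mapping keys not in class_set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  lab <- table$labels
  hit <- lab %in% names(mapping)
  lab[hit] <- unname(mapping[lab[hit]])
  if (length(unique(lab)) == 0L) {
    stop("validation error: empty class_set after grouping", call. = FALSE)
  }
  feature_table(table$values, lab, table$meta, table$sample_ids, table$codes)
}

#' Stratified train/test split
#'
#' Splits a cohort into train and test sets, stratified by class label. The
#' per-class test count is `round(test_fraction * class size)` with halves
#' rounded away from zero, so a 10% split of 1005 cancer / 812 normal
#' samples yields 101 / 81 test samples.
#'
#' @param table a [feature_table()].
#' @param test_fraction proportion in (0, 1).
#' @param seed integer; the split is deterministic given the seed.
#' @return A list of class `"split_result"` with elements `train`, `test`
#'   (both feature tables), `seed` and `test_fraction`.
#' @export
stratified_split <- function(table, test_fraction, seed) {
  stopifnot(inherits(table, "feature_table"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(table(table$labels) < 2)) {
    stop("stratification error: every class needs at least 2 samples",
         call. = FALSE)
  }
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in table$class_set) {
      idx <- which(table$labels == cl)
      n_test <- as.integer(round_half_away(test_fraction * length(idx)))
      n_test <- min(max(n_test, 0L), length(idx))
      test_idx <- c(test_idx, sort(sample(idx, n_test)))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(table$values)), test_idx)
  structure(list(train = subset_table(table, train_idx),
                 test = subset_table(table, test_idx),
                 seed = seed, test_fraction = test_fraction),
            class = "split_result")
}

#' Read a cohort table from delimited text
#'
#' Loads a CSV/TSV file with a header row into a [feature_table()]. The
#' schema names the label column and optionally assigns feature kinds,
#' routine flags and units; columns not mentioned default to biomarkers.
#' Non-numeric cells in feature columns become missing values; character
#' columns declared `clinical` are integer-coded with the code table kept.
#'
#' @param path file path.
#' @param schema list with `label` (column name), optional `id` (sample-id
#'   column), and optional `features`: a named list of
#'   `list(kind=, routine=, unit=)` entries. May also be a path to a JSON
#'   file with that structure.
#' @param sep field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A [feature_table()].
#' @export
load_feature_table <- function(path, schema, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L) {
    schema <- jsonlite::read_json(schema, simplifyVector = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("validation error: empty table", call. = FALSE)
  label_col <- schema$label
  if (is.null(label_col) || !label_col %in% names(df)) {
    stop("schema error: label column '", label_col %||% "<missing>",
         "' not present", call. = FALSE)
  }
  labels <- as.character(df[[label_col]])
  ids <- if (!is.null(schema$id) && schema$id %in% names(df)) {
    as.character(df[[schema$id]])
  } else NULL
  feat_cols <- setdiff(names(df), c(label_col, schema$id))
  if (anyDuplicated(feat_cols)) {
    stop("validation error: duplicate feature names", call. = FALSE)
  }
  spec <- schema$features %||% list()
  codes <- list()
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  kind <- character(length(feat_cols)); routine <- logical(length(feat_cols))
  unit <- character(length(feat_cols))
  for (j in seq_along(feat_cols)) {
    fc <- feat_cols[j]
    fs <- spec[[fc]] %||% list()
    kind[j] <- fs$kind %||% "biomarker"
    routine[j] <- isTRUE(fs$routine)
    unit[j] <- fs$unit %||% ""
    col <- df[[fc]]
    if (is.character(col) && kind[j] == "clinical") {
      lv <- fs$levels
      lv <- if (is.null(lv)) sort(unique(col[!is.na(col) & col != ""]))
            else unlist(lv)
      codes[[fc]] <- lv
      vals[, j] <- as.numeric(match(col, lv) - 1L)
    } else {
      vals[, j] <- suppressWarnings(as.numeric(col))
    }
  }
  feature_table(vals, labels, feature_meta(feat_cols, kind, routine, unit),
                sample_ids = ids, codes = codes)
}

#' Write a cohort table to delimited text
#'
#' Inverse of [load_feature_table()]: writes `id`, feature columns and the
#' label column. Integer-coded categorical covariates are written back as
#' their level strings so the file round-trips through the same schema.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @param sep field delimiter.
#' @param label name for the label column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = ",", label = "label") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$values, check.names = FALSE)
  for (fc in names(table$codes)) {
    df[[fc]] <- table$codes[[fc]][df[[fc]] + 1L]
  }
  df <- cbind(data.frame(id = table$sample_ids, stringsAsFactors = FALSE),
              df)
  df[[label]] <- table$labels
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Schema that reproduces a table's metadata for load_feature_table().
table_schema <- function(table, label = "label") {
  feats <- lapply(seq_len(nrow(table$meta)), function(i) {
    f <- list(kind = table$meta$kind[i], routine = table$meta$routine[i],
              unit = table$meta$unit[i])
    nm <- table$meta$name[i]
    if (nm %in% names(table$codes)) f$levels <- as.list(table$codes[[nm]])
    f
  })
  names(feats) <- table$meta$name
  list(label = label, id = "id", features = feats)
}
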