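test_that("construction validates metadata and values", {
  expect_error(feature_meta(c("a", "a")), "duplicate")
  expect_error(feature_meta("Age", kind = "clinical", routine = TRUE),
               "routine")
  v <- cbind(A = c(1, -2), B = c(3, 4))
  expect_error(feature_table(v, c("x", "y")), "negative biomarker")
  expect_error(feature_table(v[0, , drop = FALSE], character(0)), "empty")
  tab <- tiny_table()
  expect_s3_class(tab, "feature_table")
  expect_identical(dim(tab), c(20L, 3L))
})

test_that("CSV round-trip preserves values, labels, codes and metadata", {
  set.seed(9)
  n <- 12
  v <- cbind(`CA-125` = rexp(n), Age = sample(30:80, n, TRUE),
             Sex = sample(0:1, n, TRUE))
  v[3, 1] <- NA
  meta <- feature_meta(colnames(v), kind = c("biomarker", "clinical",
                                             "clinical"))
  tab <- feature_table(v, rep(c("Cancer", "Normal"), 6), meta,
                       codes = list(Sex = c("Male", "Female")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- load_feature_table(path, table_schema_of(tab))
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_identical(back$labels, tab$labels)
  expect_identical(back$sample_ids, tab$sample_ids)
  expect_identical(back$meta, tab$meta)
  expect_identical(back$codes$Sex, c("Male", "Female"))
})

test_that("loading reports schema and validation errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,CA-125,label", "s1,1.5,Cancer", "s2,0.7,Normal"), path)
  tab <- load_feature_table(path, list(label = "label", id = "id"))
  expect_identical(dim(tab), c(2L, 1L))
  expect_identical(tab$meta$kind, "biomarker")
  expect_error(load_feature_table(path, list(label = "outcome")),
               "schema error")
  # non-numeric cells in feature columns become missing
  writeLines(c("id,CA-125,label", "s1,oops,Cancer", "s2,0.7,Normal"), path)
  tab2 <- load_feature_table(path, list(label = "label", id = "id"))
  expect_true(is.na(tab2$values[1, 1]))
})

test_that("group_labels merges classes and recomputes class_set", {
  tab <- tiny_table()
  lab8 <- rep(c("Esophagus", "Stomach", "Lung", "Normal"), each = 5)
  tab8 <- feature_table(tab$values, lab8, tab$meta)
  g <- group_labels(tab8, c(Esophagus = "Upper GI", Stomach = "Upper GI"))
  expect_setequal(g$class_set, c("Upper GI", "Lung", "Normal"))
  expect_identical(nrow(g$values), nrow(tab8$values))
  # identity and idempotence
  expect_identical(group_labels(tab8, c()), tab8)
  expect_identical(group_labels(g, c(Esophagus = "Upper GI")[0]), g)
  # collapse to detection labels
  d <- group_labels(tab8, c(Esophagus = "Cancer", Stomach = "Cancer",
                            Lung = "Cancer"))
  expect_setequal(d$class_set, c("Cancer", "Normal"))
  expect_error(group_labels(tab8, c(Liver = "Cancer")), "not in class_set")
})

test_that("stratified_split obeys half-away-from-zero per-class counts", {
  set.seed(1)
  n <- 1817
  lab <- rep(c("Cancer", "Normal"), c(1005, 812))
  tab <- feature_table(cbind(A = rexp(n), B = rexp(n)), lab)
  sp <- stratified_split(tab, 0.1, seed = 11)
  cts <- table(sp$test$labels)
  expect_identical(as.integer(cts[["Cancer"]]), 101L)
  expect_identical(as.integer(cts[["Normal"]]), 81L)
  expect_identical(nrow(sp$test$values), 182L)
  # symmetric case
  tab2 <- feature_table(cbind(A = rexp(20)), rep(c("a", "b"), each = 10))
  sp2 <- stratified_split(tab2, 0.5, seed = 2)
  expect_identical(as.integer(table(sp2$test$labels)), c(5L, 5L))
  # determinism and partition properties
  sp3 <- stratified_split(tab, 0.1, seed = 11)
  expect_identical(sp3$test$sample_ids, sp$test$sample_ids)
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids),
                  tab$sample_ids)
  expect_identical(sort(c(sp$train$labels, sp$test$labels)), sort(lab))
  expect_error(stratified_split(tab, 1.2, 1), "test_fraction")
  tab1 <- feature_table(cbind(A = rexp(3)), c("a", "a", "b"))
  expect_error(stratified_split(tab1, 0.5, 1), "stratification error")
})

test_that("subset_table keeps the object consistent", {
  tab <- tiny_table()
  s <- subset_table(tab, rows = 1:5, cols = c("AFP", "CEA"))
  expect_identical(colnames(s$values), c("AFP", "CEA"))
  expect_identical(s$meta$name, c("AFP", "CEA"))
  expect_identical(s$labels, tab$labels[1:5])
  expect_error(subset_table(tab, cols = "nope"), "schema error")
})
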