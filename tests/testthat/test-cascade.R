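# Three-type cohort with cleanly separable, stage-specific markers.
cascade_cohort <- function(n = 60, seed = 1) {
  cfg <- cohort_config(
    n_per_class = c(Normal = 2 * n, Colorectal = n, Breast = n, Lung = n),
    biomarkers = feature_meta(sprintf("M%02d", 1:10)),
    informative = list(
      Colorectal = c(M01 = 8, M02 = 8),
      Breast = c(M01 = 8, M03 = 8),
      Lung = c(M01 = 8, M04 = 8)),
    correlated_pairs = list(),
    omega_shift = c(Normal = 0, Colorectal = 2, Breast = 2, Lung = 2),
    seed = seed)
  generate_cohort(cfg)
}

test_that("stage datasets shrink by the claimed class, with binary labels", {
  tab <- cascade_cohort()
  ord <- c("Colorectal", "Breast", "Lung")
  ds <- build_stage_datasets(tab, ord)
  expect_length(ds, 3)
  expect_setequal(ds[[1]]$class_set, c("Cancer", "Normal"))
  expect_identical(nrow(ds[[1]]$values), nrow(tab$values))
  expect_setequal(ds[[2]]$class_set, c("Colorectal", "other"))
  expect_setequal(ds[[3]]$class_set, c("Breast", "other"))
  # bookkeeping identity: dataset t+1 = dataset t minus the claimed class
  cts <- table(tab$labels)
  expect_identical(nrow(ds[[2]]$values),
                   as.integer(cts[["Colorectal"]] + cts[["Breast"]] +
                                cts[["Lung"]]))
  expect_identical(nrow(ds[[3]]$values),
                   nrow(ds[[2]]$values) - as.integer(cts[["Colorectal"]]))
  # two cancer types -> exactly two datasets
  two <- subset_table(tab, rows = which(tab$labels != "Lung"))
  expect_length(build_stage_datasets(two, c("Colorectal", "Breast")), 2)
  expect_error(build_stage_datasets(two, c("Colorectal", "Breast", "Lung")),
               "zero samples")
  expect_error(build_stage_datasets(two, "Colorectal"), ">= 2")
})

test_that("a separable cohort fits a cascade with perfect stage metrics", {
  tab <- cascade_cohort(n = 40, seed = 3)
  cas <- fit_cascade(tab, class_order = c("Colorectal", "Breast", "Lung"),
                     n_rounds = 2, top_k = 5,
                     space = search_space(n_estimators = 30L,
                                          num_leaves = 7L,
                                          n_iterations = 2L),
                     k = 4, seed = 11)
  expect_length(cas$stages, 3)
  expect_identical(cas$stages[[1]]$positive, "Cancer")
  for (s in cas$stages) {
    expect_equal(s$test_metrics$balanced_accuracy, 1)
  }
  # stage feature sets may differ: each typing stage leans on its marker
  sel2 <- cas$stages[[2]]$selection$selected
  sel3 <- cas$stages[[3]]$selection$selected
  expect_true("M02" %in% sel2)
  expect_true("M03" %in% sel3)
})

test_that("cascade prediction is total, consistent and order-equivariant", {
  tab <- cascade_cohort(n = 40, seed = 3)
  cas <- fit_cascade(tab, class_order = c("Colorectal", "Breast", "Lung"),
                     n_rounds = 2, top_k = 5,
                     space = search_space(n_estimators = 30L,
                                          num_leaves = 7L,
                                          n_iterations = 2L),
                     k = 4, seed = 11)
  pred <- predict(cas, tab)
  expect_length(pred, nrow(tab$values))
  expect_true(all(pred %in% c("Normal", cas$class_order)))
  expect_false(anyNA(pred))
  # separable cohort: predictions recover the true labels
  expect_gt(mean(pred == tab$labels), 0.97)
  # permuting samples permutes predictions identically
  perm <- sample(nrow(tab$values))
  pred_perm <- predict(cas, subset_table(tab, rows = perm))
  expect_identical(pred_perm, pred[perm])
})

test_that("detection short-circuit and last-class fallback rules hold", {
  tab <- cascade_cohort(n = 40, seed = 5)
  cas <- fit_cascade(tab, class_order = c("Colorectal", "Breast", "Lung"),
                     n_rounds = 2, top_k = 5,
                     space = search_space(n_estimators = 20L,
                                          num_leaves = 7L,
                                          n_iterations = 1L),
                     k = 3, seed = 13)
  # force the detection stage negative: everything is Normal
  cas0 <- cas
  cas0$stages[[1]]$ensemble$threshold <- 1.01
  expect_identical(unique(predict(cas0, tab)), "Normal")
  # force detection positive and every typing stage negative: last class
  cas1 <- cas
  cas1$stages[[1]]$ensemble$threshold <- 0
  cas1$stages[[2]]$ensemble$threshold <- 1.01
  cas1$stages[[3]]$ensemble$threshold <- 1.01
  expect_identical(unique(predict(cas1, tab)), "Lung")
})
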