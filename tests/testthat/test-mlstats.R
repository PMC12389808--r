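test_that("stratified folds balance classes and reject tiny groups", {
  labels <- rep(c(0.1, 0.5, 1.0), each = 9)
  folds <- make_stratified_folds(labels, k = 3, seed = 1)
  expect_equal(sort(unique(folds)), 1:3)
  for (f in 1:3)
    expect_equal(as.integer(table(labels[folds == f])), rep(3L, 3))
  expect_identical(folds, make_stratified_folds(labels, k = 3, seed = 1))
  expect_error(make_stratified_folds(c(0.1, 0.1, 0.5), k = 3), "at least k")
})

test_that("every family separates well-separated one-feature classes", {
  ds <- separable_dataset(per_class = 6)
  for (fam in classifier_families()) {
    grid <- model_grid(fam, head(default_grid(fam), 2))
    cv <- grid_search_cv(ds, grid, seed = 1)
    expect_equal(cv$cv_accuracy_mean, 1.0,
                 info = paste("family:", fam))
  }
})

test_that("grid search honours enumeration order and single-point grids", {
  ds <- separable_dataset(per_class = 6)
  single <- model_grid("knn", data.frame(k = 3))
  cv <- grid_search_cv(ds, single, seed = 2)
  expect_equal(cv$best_params$k, 3)
  expect_equal(nrow(cv$results), 1)

  # all grid points tie at accuracy 1; the first must be selected
  tie <- model_grid("knn", data.frame(k = c(5, 1, 3)))
  cv2 <- grid_search_cv(ds, tie, seed = 2)
  expect_equal(cv2$best_params$k, 5)
  expect_equal(cv2$results$cv_accuracy_mean, rep(1, 3))
})

test_that("CV accuracy is invariant to feature and sample permutation", {
  withr::with_seed(31, {
    m <- cbind(rep(c(1, 2, 3), each = 6) + rnorm(18, 0, 0.3),
               matrix(rnorm(18 * 4), nrow = 18))
  })
  ds <- profile_dataset(m, labels = rep(c(0.1, 0.5, 1.0), each = 6),
                        groups = rep(1:6, 3))
  folds <- make_stratified_folds(ds$labels, seed = 5)
  grid <- model_grid("svm", data.frame(kernel = "linear", cost = 1,
                                       gamma = NA))
  base <- grid_search_cv(ds, grid, folds = folds)

  perm_f <- withr::with_seed(6, sample(ncol(m)))
  ds_f <- profile_dataset(m[, perm_f], ds$labels, ds$groups)
  expect_equal(grid_search_cv(ds_f, grid, folds = folds)$cv_accuracy_mean,
               base$cv_accuracy_mean)

  perm_s <- withr::with_seed(7, sample(nrow(m)))
  ds_s <- profile_dataset(m[perm_s, ], ds$labels[perm_s],
                          ds$groups[perm_s])
  expect_equal(grid_search_cv(ds_s, grid,
                              folds = folds[perm_s])$cv_accuracy_mean,
               base$cv_accuracy_mean)
})

test_that("report metrics match hand computation from the pooled matrix", {
  withr::with_seed(13, {
    m <- matrix(rep(c(1, 2, 3), each = 8) + rnorm(24, 0, 0.8), ncol = 1)
  })
  ds <- profile_dataset(m, labels = rep(c(0.1, 0.5, 1.0), each = 8),
                        groups = rep(1:8, 3))
  rep_ <- evaluate_report(ds, "knn", data.frame(k = 3), seed = 3)

  cm <- rep_$confusion
  expect_equal(sum(cm), 24)                        # entries sum to n
  expect_equal(unname(rowSums(cm)), rep(8, 3))     # row sums = class counts
  expect_equal(rep_$accuracy, sum(diag(cm)) / sum(cm))
  for (i in 1:3) {
    expect_equal(rep_$per_class$precision[i],
                 diag(cm)[i] / max(sum(cm[, i]), 1), ignore_attr = TRUE)
    expect_equal(rep_$per_class$recall[i], diag(cm)[i] / sum(cm[i, ]),
                 ignore_attr = TRUE)
    p <- rep_$per_class$precision[i]; r <- rep_$per_class$recall[i]
    expect_equal(rep_$per_class$f1[i],
                 if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  expect_equal(unname(rep_$macro["f1"]), mean(rep_$per_class$f1))
})

test_that("degenerate classifiers produce the closed-form report", {
  ds <- separable_dataset(per_class = 6)
  perfect <- evaluate_report(ds, "knn", data.frame(k = 1), seed = 1)
  expect_equal(unname(diag(perfect$confusion)), rep(6, 3))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$macro), c(1, 1, 1))

  # constant features: the tree cannot split and predicts one class
  const <- profile_dataset(matrix(1, nrow = 18, ncol = 2),
                           labels = rep(c(0.1, 0.5, 1.0), each = 6),
                           groups = rep(1:6, 3))
  rep_c <- evaluate_report(const, "decision_tree",
                           data.frame(maxdepth = 3), seed = 1)
  expect_equal(rep_c$accuracy, 1 / 3)
  expect_equal(sum(colSums(rep_c$confusion) > 0), 1)   # one nonzero column
})

test_that("ANOVA F matches the mean-square ratio on a toy table", {
  # 3 groups x 5 values, computed independently from the definition
  vals <- c(1.1, 0.9, 1.0, 1.2, 0.8,
            2.0, 2.2, 1.8, 2.1, 1.9,
            2.9, 3.1, 3.0, 2.8, 3.2)
  g <- rep(c("a1", "a2", "a3"), each = 5)
  at <- anova_tukey(vals, g)

  gm <- mean(vals)
  means <- tapply(vals, g, mean)
  ms_between <- 5 * sum((means - gm)^2) / (3 - 1)
  ms_within <- sum((vals - means[g])^2) / (15 - 3)
  expect_equal(at$F, ms_between / ms_within)
  expect_lt(at$p, 0.05)
  expect_equal(unname(at$letters[c("a3", "a2", "a1")]), c("a", "b", "c"))
})

test_that("zero within-group variance separates groups absolutely", {
  at <- anova_tukey(rep(c(1, 2, 3), each = 3), rep(c("x", "y", "z"), each = 3))
  expect_equal(at$F, Inf)
  expect_equal(at$p, 0)
  expect_equal(sort(unname(at$letters)), c("a", "b", "c"))
  expect_true(all(at$table$p_adj == 0))

  # identical constant groups: no variance anywhere, p undefined
  flat <- anova_tukey(rep(1, 9), rep(c("x", "y", "z"), each = 3))
  expect_true(is.na(flat$p))
  expect_equal(unname(flat$letters), rep("a", 3))
})

test_that("close groups share a letter, distant ones do not", {
  withr::with_seed(17, {
    v <- c(rnorm(10, 10, 1), rnorm(10, 10.1, 1), rnorm(10, 30, 1))
  })
  at <- anova_tukey(v, rep(c("g1", "g2", "g3"), each = 10))
  expect_equal(unname(at$letters["g3"]), "a")     # largest mean, alone
  expect_equal(unname(at$letters["g1"]), unname(at$letters["g2"]))
  expect_error(anova_tukey(1:4, c("x", "x", "x", "y")), "at least 2 values")
})

test_that("family comparison shares folds and mirrors per-family search", {
  ds <- separable_dataset(per_class = 6)
  tab <- compare_families(ds, families = c("svm", "knn", "lda"), seed = 4)
  expect_equal(tab$family, c("svm", "knn", "lda"))
  expect_true(all(tab$cv_accuracy_mean == 1))
  res <- attr(tab, "cv_results")
  expect_identical(res$svm$folds, res$lda$folds)
})
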