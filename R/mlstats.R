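#' Supported classifier families
#'
#' The eight families compared by the pipeline: support vector machine
#' (e1071), multinomial logistic regression (nnet; the classification analog
#' of a "linear regression" baseline), single-hidden-layer perceptron (nnet),
#' k-nearest neighbors (class), random forest (randomForest), linear
#' discriminant analysis (MASS), Gaussian naive Bayes (e1071), and decision
#' tree (rpart).
#'
#' @return Character vector of family names.
#' @export
classifier_families <- function() {
  c("svm", "logistic", "mlp", "knn", "random_forest", "lda", "gaussian_nb",
    "decision_tree")
}

#' Default hyperparameter grid for a family
#'
#' Grids are package defaults (configurable), kept small enough for
#' exhaustive search. `NA` entries mean "library default" (e.g. the SVM
#' kernel width heuristic `1/n_features`, or an unrestricted tree).
#'
#' @param family one of [classifier_families()].
#' @return A data frame, one row per hyperparameter combination.
#' @export
default_grid <- function(family) {
  switch(
    match.arg(family, classifier_families()),
    svm = rbind(
      expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100),
                  gamma = NA, stringsAsFactors = FALSE),
      expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                  gamma = c(NA, 0.01, 0.1, 1), stringsAsFactors = FALSE)),
    logistic = data.frame(decay = c(0, 0.01, 0.1)),
    mlp = expand.grid(size = c(8, 32, 128), decay = c(1e-4, 1e-2)),
    knn = data.frame(k = c(1, 3, 5, 7)),
    random_forest = expand.grid(ntree = c(100, 300, 500),
                                maxnodes = c(NA, 8, 1024)),
    lda = data.frame(method = c("moment", "mle"),
                     stringsAsFactors = FALSE),
    gaussian_nb = data.frame(laplace = 0),
    decision_tree = data.frame(maxdepth = c(30, 3, 5))
  )
}

#' Hyperparameter grid specification
#'
#' @param family one of [classifier_families()].
#' @param grid data frame of hyperparameter combinations (default
#'   [default_grid()]).
#' @param seed integer seed for the family's stochastic parts (forest
#'   bootstraps, network initialization, kNN tie-breaks).
#' @return An object of class `model_grid`.
#' @export
model_grid <- function(family, grid = default_grid(family), seed = 1L) {
  family <- match.arg(family, classifier_families())
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_grid")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently under the seed and deals its samples
#' round-robin into `k` folds, so every fold holds (as nearly as possible)
#' the same class proportions.
#'
#' @param labels class label per sample.
#' @param k number of folds (default 3).
#' @param seed integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_stratified_folds <- function(labels, k = 3L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs at least k = ", k, " samples; smallest has ",
         min(counts))
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Train one family on (x_train, y_train) and predict x_test.
# `params` is a one-row data frame from the family's grid.
fit_and_predict <- function(family, params, x_train, y_train, x_test,
                            seed = 1L) {
  y_train <- droplevels(as.factor(y_train))
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  colnames(x_train) <- colnames(x_test) <- paste0("f", seq_len(ncol(x_train)))

  # LDA and Gaussian NB cannot digest zero-variance predictors
  if (family %in% c("lda", "gaussian_nb")) {
    keep <- apply(x_train, 2, function(col) stats::sd(col) > 0)
    if (!any(keep)) keep[1] <- TRUE
    x_train <- x_train[, keep, drop = FALSE]
    x_test <- x_test[, keep, drop = FALSE]
  }

  pred <- withr::with_seed(seed, switch(
    family,
    svm = {
      gamma <- if (is.na(params$gamma)) 1 / ncol(x_train) else params$gamma
      fit <- e1071::svm(x_train, y_train, kernel = as.character(params$kernel),
                        cost = params$cost, gamma = gamma, scale = FALSE)
      predict(fit, x_test)
    },
    logistic = {
      df <- data.frame(.y = y_train, x_train, check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = df, decay = params$decay,
                            trace = FALSE, MaxNWts = 100000)
      predict(fit, newdata = as.data.frame(x_test), type = "class")
    },
    mlp = {
      fit <- nnet::nnet(x_train, nnet::class.ind(y_train),
                        size = params$size, decay = params$decay,
                        softmax = TRUE, maxit = 300, MaxNWts = 1000000,
                        trace = FALSE)
      p <- predict(fit, x_test)
      factor(levels(y_train)[max.col(p)], levels = levels(y_train))
    },
    knn = class::knn(x_train, x_test, y_train, k = params$k),
    random_forest = {
      maxnodes <- if (is.na(params$maxnodes)) NULL else params$maxnodes
      fit <- randomForest::randomForest(x_train, y_train,
                                        ntree = params$ntree,
                                        maxnodes = maxnodes)
      predict(fit, x_test)
    },
    lda = {
      fit <- MASS::lda(x_train, grouping = y_train,
                       method = as.character(params$method))
      predict(fit, x_test)$class
    },
    gaussian_nb = {
      fit <- e1071::naiveBayes(x_train, y_train, laplace = params$laplace)
      predict(fit, x_test)
    },
    decision_tree = {
      df <- data.frame(.y = y_train, x_train, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = params$maxdepth, minsplit = 2,
                            minbucket = 1, xval = 0))
      predict(fit, newdata = as.data.frame(x_test), type = "class")
    },
    stop("unknown family: ", family)
  ))
  factor(as.character(pred), levels = levels(as.factor(y_train)))
}

#' Grid-searched stratified k-fold cross-validation
#'
#' Evaluates every hyperparameter combination of the grid with the same
#' stratified `k`-fold split and returns the combination with the highest
#' mean CV accuracy (ties broken by grid enumeration order). The reported
#' accuracy is that same CV score -- the selection protocol is deliberately
#' not nested.
#'
#' @param dataset a [profile_dataset()].
#' @param grid a [model_grid()] (or a family name, using its default grid).
#' @param k number of folds (default 3).
#' @param seed seed for the fold shuffle and the family's stochastic parts.
#' @param folds optional precomputed fold assignment (overrides `k`/`seed`
#'   for the split).
#' @return An object of class `cv_result`: list with `family`, `best_params`
#'   (one-row data frame), `cv_accuracy_mean`, `cv_accuracy_sd`,
#'   `fold_accuracies`, `results` (the grid with per-combination scores),
#'   `folds`.
#' @export
grid_search_cv <- function(dataset, grid, k = 3L, seed = 1L, folds = NULL) {
  stopifnot(inherits(dataset, "profile_dataset"))
  if (is.character(grid)) grid <- model_grid(grid, seed = seed)
  stopifnot(inherits(grid, "model_grid"))
  if (!all(is.finite(dataset$matrix))) stop("features must be finite")
  y <- as.factor(dataset$labels)
  folds <- folds %||% make_stratified_folds(y, k = k, seed = seed)
  k <- max(folds)
  g <- grid$grid
  acc <- matrix(NA_real_, nrow = nrow(g), ncol = k)
  for (i in seq_len(nrow(g))) {
    for (f in seq_len(k)) {
      test <- folds == f
      pred <- fit_and_predict(grid$family, g[i, , drop = FALSE],
                              dataset$matrix[!test, , drop = FALSE], y[!test],
                              dataset$matrix[test, , drop = FALSE],
                              seed = fold_seed(seed, i, f))
      acc[i, f] <- mean(pred == y[test])
    }
  }
  means <- rowMeans(acc)
  best <- which.max(means)   # first maximum = grid enumeration order
  results <- cbind(g, cv_accuracy_mean = means,
                   cv_accuracy_sd = apply(acc, 1, sd))
  structure(
    list(family = grid$family, best_params = g[best, , drop = FALSE],
         cv_accuracy_mean = means[best],
         cv_accuracy_sd = sd(acc[best, ]),
         fold_accuracies = acc[best, ], results = results, folds = folds,
         k = k, seed = seed),
    class = "cv_result"
  )
}

fold_seed <- function(seed, i, f) (as.integer(seed) %% 1000000L) +
  7919L * i + 101L * f

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: accuracy %.3f (sd %.3f) over %d folds\n",
              x$family, x$cv_accuracy_mean, x$cv_accuracy_sd, x$k))
  cat("  best params:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated classification report for one model
#'
#' Refits the family at fixed hyperparameters on each training fold,
#' pools the out-of-fold predictions into a single confusion matrix, and
#' derives per-class and macro precision/recall/F1 from that matrix.
#' Accuracy mean and sd are computed across folds.
#'
#' @param dataset a [profile_dataset()].
#' @param family one of [classifier_families()].
#' @param params one-row data frame of hyperparameters (e.g.
#'   `cv$best_params`).
#' @param k,seed,folds as in [grid_search_cv()].
#' @return An object of class `classification_report`: `confusion`
#'   (truth x prediction table), `accuracy`, `accuracy_mean`, `accuracy_sd`,
#'   `per_class` (precision/recall/F1 per class), `macro` (their means).
#' @export
evaluate_report <- function(dataset, family, params, k = 3L, seed = 1L,
                            folds = NULL) {
  stopifnot(inherits(dataset, "profile_dataset"))
  y <- as.factor(dataset$labels)
  folds <- folds %||% make_stratified_folds(y, k = k, seed = seed)
  k <- max(folds)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    pred[test] <- fit_and_predict(family, params,
                                  dataset$matrix[!test, , drop = FALSE],
                                  y[!test],
                                  dataset$matrix[test, , drop = FALSE],
                                  seed = fold_seed(seed, 1L, f))
    fold_acc[f] <- mean(pred[test] == y[test])
  }
  confusion <- table(truth = y, prediction = pred)
  tp <- diag(confusion)
  precision <- tp / pmax(colSums(confusion), 1)
  recall <- tp / pmax(rowSums(confusion), 1)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = levels(y), precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1))
  structure(
    list(family = family, params = params, confusion = confusion,
         accuracy = sum(tp) / sum(confusion),
         accuracy_mean = mean(fold_acc), accuracy_sd = sd(fold_acc),
         fold_accuracies = fold_acc, per_class = per_class,
         macro = c(precision = mean(precision), recall = mean(recall),
                   f1 = mean(f1)),
         folds = folds),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report [%s]: pooled accuracy %.3f (fold mean %.3f, sd %.3f)\n",
              x$family, x$accuracy, x$accuracy_mean, x$accuracy_sd))
  print(x$confusion)
  print(x$per_class, row.names = FALSE, digits = 3)
  cat(sprintf("  macro: precision %.3f, recall %.3f, F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' Compare classifier families on one dataset
#'
#' Runs [grid_search_cv()] for each requested family with a shared fold
#' split and tabulates the best CV accuracy per family -- the layout of a
#' model-comparison table.
#'
#' @param dataset a [profile_dataset()].
#' @param families character vector of families (default all eight).
#' @param grids optional named list of [model_grid()]s overriding defaults.
#' @param k,seed as in [grid_search_cv()].
#' @return A data frame: `family`, `cv_accuracy_mean`, `cv_accuracy_sd`,
#'   `best_params` (deparsed), with the per-family `cv_result`s attached as
#'   attribute `"cv_results"`.
#' @export
compare_families <- function(dataset, families = classifier_families(),
                             grids = NULL, k = 3L, seed = 1L) {
  folds <- make_stratified_folds(dataset$labels, k = k, seed = seed)
  res <- lapply(families, function(fam) {
    g <- grids[[fam]] %||% model_grid(fam, seed = seed)
    grid_search_cv(dataset, g, seed = seed, folds = folds)
  })
  names(res) <- families
  out <- data.frame(
    family = families,
    cv_accuracy_mean = vapply(res, `[[`, 0, "cv_accuracy_mean"),
    cv_accuracy_sd = vapply(res, `[[`, 0, "cv_accuracy_sd"),
    best_params = vapply(res, function(r)
      paste(names(r$best_params), unlist(r$best_params), sep = "=",
            collapse = ", "), ""),
    row.names = NULL
  )
  attr(out, "cv_results") <- res
  out
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Tests whether the fit coefficients differ between concentration classes:
#' one-way fixed-effects ANOVA, Tukey honest-significant-difference adjusted
#' pairwise comparisons, and a compact letter display in which groups sharing
#' no letter differ at level `alpha`. Letters are assigned in order of
#' decreasing group mean (fastest flow gets "a").
#'
#' When every group has zero within-group variance the F statistic is not
#' defined; pairwise significance then degenerates to "means differ or not"
#' and `F`/`p` are reported as `NaN`/`NA`.
#'
#' @param values numeric response (e.g. fitted slopes `a`).
#' @param labels group label per value.
#' @param alpha familywise significance level (default 0.05).
#' @return An object of class `anova_tukey`: `F`, `p`, `table` (pairwise
#'   diff/lwr/upr/p_adj), `letters` (named character vector by group),
#'   `means`, `alpha`.
#' @examples
#' anova_tukey(c(1, 1.1, 0.9, 2, 2.1, 1.9, 3, 3.1, 2.9),
#'             rep(c("0.1", "0.5", "1.0"), each = 3))
#' @export
anova_tukey <- function(values, labels, alpha = 0.05) {
  g <- droplevels(as.factor(labels))
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("need at least 2 values per group")
  means <- tapply(values, g, mean)
  df <- data.frame(y = as.numeric(values), g = g)
  fit <- aov(y ~ g, data = df)
  ss <- summary(fit)[[1]]
  mse <- ss["Residuals", "Mean Sq"]
  Fstat <- ss[1, "F value"]
  pval <- ss[1, "Pr(>F)"]

  if (!is.finite(mse) || mse <= .Machine$double.eps * max(abs(values), 1)) {
    # all residual variance gone: any mean difference is infinitely separated
    pairs <- utils::combn(levels(g), 2)
    diffs <- means[pairs[2, ]] - means[pairs[1, ]]
    p_adj <- ifelse(abs(diffs) > 0, 0, 1)
    tab <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                      diff = as.numeric(diffs), lwr = NA_real_,
                      upr = NA_real_, p_adj = p_adj)
    Fstat <- if (any(abs(diffs) > 0)) Inf else NaN
    pval <- if (any(abs(diffs) > 0)) 0 else NA_real_
  } else {
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
    tab <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  }

  sig <- matrix(FALSE, nlevels(g), nlevels(g),
                dimnames = list(levels(g), levels(g)))
  for (r in seq_len(nrow(tab))) {
    pr <- strsplit(tab$pair[r], "-", fixed = TRUE)[[1]]
    s <- is.finite(tab$p_adj[r]) && tab$p_adj[r] < alpha
    sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- s
  }
  letters <- compact_letters(sig, order(means, decreasing = TRUE))

  structure(
    list(F = Fstat, p = pval, table = tab, letters = letters,
         means = means, alpha = alpha),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g (alpha = %g)\n",
              x$F, x$p, x$alpha))
  df <- data.frame(group = names(x$means), mean = as.numeric(x$means),
                   letters = x$letters[names(x$means)])
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

# Compact letter display by insert-and-absorb on a pairwise significance
# matrix. `ord` gives the group order in which letters are assigned.
compact_letters <- function(sig, ord = seq_len(nrow(sig))) {
  n <- nrow(sig)
  groups <- rownames(sig)
  cols <- list(rep(TRUE, n))  # letter columns: logical membership vectors
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!sig[i, j]) next
      hit <- vapply(cols, function(cl) cl[i] && cl[j], TRUE)
      if (!any(hit)) next
      new_cols <- cols[!hit]
      for (cl in cols[hit]) {
        c1 <- cl; c1[i] <- FALSE
        c2 <- cl; c2[j] <- FALSE
        new_cols <- c(new_cols, list(c1), list(c2))
      }
      # absorb columns that are subsets of another; drop duplicates
      keep <- rep(TRUE, length(new_cols))
      for (p in seq_along(new_cols)) {
        for (q in seq_along(new_cols)) {
          if (p == q || !keep[p]) next
          sub_pq <- all(!new_cols[[p]] | new_cols[[q]])
          if (sub_pq && (!all(new_cols[[p]] == new_cols[[q]]) || p > q))
            keep[p] <- FALSE
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by the first (in `ord`) group they contain, assign letters
  first_member <- vapply(cols, function(cl) min(match(which(cl), ord)), 0)
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(n), function(gi)
    paste(letters[which(vapply(cols, `[[`, TRUE, gi))], collapse = ""), "")
  names(out) <- groups
  out
}

#' Write Tukey letters as a two-column CSV
#'
#' @param at an [anova_tukey()] result.
#' @param path CSV output path (columns: class, letters).
#' @return `path`, invisibly.
#' @export
write_letters_csv <- function(at, path) {
  stopifnot(inherits(at, "anova_tukey"))
  write.csv(data.frame(class = names(at$letters), letters = at$letters,
                       row.names = NULL),
            path, row.names = FALSE)
  invisible(path)
}
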