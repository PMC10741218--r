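#' Default hyperparameter grids for the four classifiers
#'
#' Small lattices: logistic regression (ridge strength, 4 values), SVM
#' (linear/RBF kernel x cost, 6 cells), random forest (trees x depth cap),
#' XGBoost (depth x learning rate, 4 cells).
#'
#' @return Named list of data.frame grids keyed by `"LR"`, `"SVM"`, `"RF"`,
#'   `"XGB"`.
#' @export
default_grids <- function() {
  list(
    LR = data.frame(lambda = c(1e-4, 0.01, 0.1, 1)),
    SVM = expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    RF = expand.grid(ntree = c(100, 300), maxnodes = c(8, 32, 128)),
    XGB = expand.grid(max_depth = c(2, 4), eta = c(0.1, 0.3))
  )
}

fit_one <- function(x, y, classifier, par, seed) {
  set.seed(as.integer(seed))
  yf <- factor(y, levels = sort(unique(y)))
  switch(classifier,
    LR = {
      # ridge-penalized logit; the lambda grid spans near-unpenalized to
      # strongly regularized
      fit <- glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                            lambda = par$lambda)
      list(kind = "glmnet", fit = fit, lambda = par$lambda)
    },
    SVM = {
      fit <- e1071::svm(x, yf, kernel = par$kernel, cost = par$cost,
                        scale = FALSE)
      list(kind = "svm", fit = fit)
    },
    RF = {
      # a terminal-node cap above n is meaningless; clamp silently
      maxn <- min(par$maxnodes, max(2L, nrow(x)))
      fit <- randomForest::randomForest(x, yf, ntree = par$ntree,
                                        maxnodes = maxn)
      list(kind = "rf", fit = fit)
    },
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(data = x,
                                     label = as.integer(yf) - 1L,
                                     nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = par$max_depth, eta = par$eta,
                      nthread = 1),
        data = dtrain, nrounds = 50, verbose = 0)
      list(kind = "xgb", fit = fit, levels = levels(yf))
    },
    stop("unknown classifier '", classifier, "'", call. = FALSE))
}

predict_one <- function(model, x) {
  switch(model$kind,
    glmnet = {
      as.character(stats::predict(model$fit, newx = x, type = "class",
                                  s = model$lambda))
    },
    svm = as.character(stats::predict(model$fit, x)),
    rf = as.character(stats::predict(model$fit, x)),
    xgb = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1))
      model$levels[1L + as.integer(p > 0.5)]
    })
}

#' Grid-searched fit and prediction for one classifier
#'
#' Inner stratified 5-fold cross-validation on the training set scores every
#' grid cell by accuracy; the best cell (first on ties, in grid order) is
#' refit on the full training set and used to predict the test set. A grid
#' of size 1 is a direct fit.
#'
#' @param train,test `feature_matrix` objects sharing columns; `train` must
#'   carry a binary target.
#' @param classifier `"LR"`, `"SVM"`, `"RF"` or `"XGB"`.
#' @param grid Data.frame of hyperparameter combinations (defaults to the
#'   classifier's entry in [default_grids()]).
#' @param seed Integer seed (controls inner folds and stochastic fits).
#' @param inner_folds Inner CV folds for the grid search (default 5).
#' @return List with `predictions` (character vector for `test` rows),
#'   `hyperparameters` (the chosen row), and `inner_accuracy`.
#' @export
grid_fit_predict <- function(train, test, classifier, grid = NULL,
                             seed = 1, inner_folds = 5) {
  if (!classifier %in% c("LR", "SVM", "RF", "XGB")) {
    stop("unknown classifier '", classifier, "'", call. = FALSE)
  }
  if (is.null(grid)) grid <- default_grids()[[classifier]]
  if (!nrow(grid)) stop("empty hyperparameter grid", call. = FALSE)
  x <- train$values; y <- train$target
  if (nrow(grid) == 1L) {
    best <- 1L; best_acc <- NA_real_
  } else {
    inner_folds <- min(inner_folds, min(table(y)))
    fold_id <- stratified_folds(y, inner_folds, seed = seed)
    accs <- vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0L; total <- 0L
      for (f in seq_len(inner_folds)) {
        tr <- fold_id != f
        model <- fit_one(x[tr, , drop = FALSE], y[tr], classifier,
                         grid[g, , drop = FALSE], seed + f)
        pred <- predict_one(model, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == as.character(y[!tr]))
        total <- total + sum(!tr)
      }
      correct / total
    }, 0)
    best <- which.max(accs); best_acc <- accs[best]
  }
  model <- fit_one(x, y, classifier, grid[best, , drop = FALSE], seed)
  list(predictions = predict_one(model, test$values),
       hyperparameters = grid[best, , drop = FALSE],
       inner_accuracy = if (nrow(grid) == 1L) NA_real_ else best_acc)
}

#' Benchmark classifiers on the consensus features
#'
#' Repeated stratified k-fold cross-validation: per outer fold, the top-20
#' consensus features are extracted, training rows are imputed, normalized
#' and SMOTE-balanced, each classifier is grid-searched and refit, and test
#' accuracy is recorded. The baseline is the majority-class share.
#'
#' @param fm The full `feature_matrix` (binary target).
#' @param selection A `selection_result`; its `top20` defines the feature
#'   set (a character vector of feature names is also accepted).
#' @param classifiers Subset of `c("LR", "SVM", "RF", "XGB")`.
#' @param repeats,folds Outer CV geometry (default 10 x 10).
#' @param grids Optional named list of grids (see [default_grids()]).
#' @param seed Integer seed.
#' @param label Dataset label carried into the report (e.g. `"overall"`).
#' @return A `benchmark_report`: `accuracy` (classifier x 1 mean test
#'   accuracy), `per_fold`, `baseline`, `label`.
#' @export
evaluate_classifiers <- function(fm, selection,
                                 classifiers = c("LR", "SVM", "RF", "XGB"),
                                 repeats = 10, folds = 10, grids = NULL,
                                 seed = 1, label = "overall") {
  feats <- if (inherits(selection, "selection_result")) {
    selection$top20
  } else as.character(selection)
  feats <- intersect(feats, colnames(fm$values))
  if (!length(feats)) stop("no selected features present", call. = FALSE)
  sub <- fm
  keep <- match(feats, colnames(fm$values))
  sub$values <- fm$values[, keep, drop = FALSE]
  sub$map <- fm$map[keep, , drop = FALSE]
  y <- sub$target
  if (length(unique(y)) != 2) {
    stop("binary target with both classes required", call. = FALSE)
  }
  if (is.null(grids)) grids <- default_grids()
  baseline <- max(table(y)) / length(y)
  acc <- matrix(NA_real_, repeats * folds, length(classifiers),
                dimnames = list(NULL, classifiers))
  row_i <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds, seed = seed * 1000L + r)
    for (f in seq_len(folds)) {
      row_i <- row_i + 1L
      tr_rows <- which(fold_id != f)
      te_rows <- which(fold_id == f)
      train <- prep_fold(sub, tr_rows, smote = TRUE,
                         seed = seed * 100000L + r * 100L + f)
      test <- sub
      test$values <- sub$values[te_rows, , drop = FALSE]
      test$target <- y[te_rows]
      if (anyNA(test$values)) test <- knn_impute(test, k = 5)
      # apply the training fold's normalization semantics to the test side
      test <- normalize_features(test)
      for (cl in classifiers) {
        res <- grid_fit_predict(train, test, cl, grid = grids[[cl]],
                                seed = seed + row_i)
        acc[row_i, cl] <- mean(res$predictions == as.character(test$target))
      }
    }
  }
  structure(list(accuracy = colMeans(acc), per_fold = acc,
                 baseline = baseline, label = label,
                 features = feats, repeats = repeats, folds = folds,
                 seed = seed),
            class = "benchmark_report")
}

#' @export
#' @method print benchmark_report
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> [", x$label, "] baseline ",
      sprintf("%.3f", x$baseline), "\n", sep = "")
  for (cl in names(x$accuracy)) {
    cat(sprintf("  %-4s mean accuracy %.3f\n", cl, x$accuracy[[cl]]))
  }
  invisible(x)
}

#' Write a benchmark report as JSON and CSV
#'
#' @param report A `benchmark_report`.
#' @param path Base path (writes `<path>.json` and `<path>.csv`).
#' @return The base path, invisibly.
#' @export
write_benchmark <- function(report, path) {
  jsonlite::write_json(
    list(label = report$label, baseline = report$baseline,
         accuracy = as.list(report$accuracy),
         repeats = report$repeats, folds = report$folds),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(
    data.frame(classifier = names(report$accuracy),
               mean_accuracy = unname(report$accuracy),
               baseline = report$baseline),
    paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
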