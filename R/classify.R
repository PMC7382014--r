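# Record-level diagnosis models on the 848-feature table.
#
# Four classical algorithms -- logistic regression (LR), RBF-kernel support
# vector machine (SVM), CART decision tree (DT) and random forest (RF) --
# evaluated by subject-grouped stratified k-fold cross-validation.  Grouping
# by subject matters: each subject contributes ~3 records, and letting them
# straddle the train/test boundary lets the models recognize *identity*
# rather than disease.

ALGORITHMS <- c("lr", "svm", "dt", "rf")

.fit_algo <- function(algo, x, y01, num_trees = 100) {
  switch(algo,
         lr = fit_lr(x, y01),
         svm = fit_svm(x, y01),
         dt = fit_tree(x, y01),
         rf = fit_forest(x, y01, num_trees = num_trees),
         stop("unknown algorithm '", algo, "'"))
}

.predict_algo <- function(model, x) {
  switch(model$kind,
         lr = predict_lr(model, x),
         svm = predict_svm(model, x),
         tree = predict_tree(model, x),
         forest = predict_forest(model, x),
         stop("unknown model kind '", model$kind, "'"))
}

.needs_standardization <- function(algo) algo %in% c("lr", "svm")

#' Cross-validated evaluation of the classical classifiers
#'
#' Subject-grouped stratified k-fold CV; predictions are pooled over folds
#' and summarized as precision / recall / F1 with PD as the positive class.
#' Features are standardized (train-fold statistics) for LR and SVM; trees
#' and forests see raw features.
#'
#' @param table A [feature_table()].
#' @param algorithms Subset of `c("lr", "svm", "dt", "rf")`.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold assignment and the stochastic
#'   learners.
#' @param average Metric averaging, see [classification_metrics()].
#' @param num_trees Trees in the random forest.
#' @return Object of class `classification_report`: list with `metrics`
#'   (data.frame algorithm x precision/recall/f1/accuracy), `confusion`
#'   (per algorithm), `per_fold`, `folds`, `seed`.
#' @export
evaluate_classifiers <- function(table, algorithms = ALGORITHMS, folds = 5,
                                 seed = 1L, average = "binary",
                                 num_trees = 100) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  parts <- split_feature_table(table)
  if (length(unique(parts$groups[parts$y == 1])) < 2 ||
      length(unique(parts$groups[parts$y == 0])) < 2) {
    stop("need >= 2 subjects per class")
  }
  fold_id <- grouped_folds(parts$groups, parts$labels, k = folds, seed = seed)
  for (f in seq_len(folds)) {
    if (length(unique(parts$y[fold_id != f])) < 2) {
      stop("fold ", f, " leaves a single-class training set; ",
           "use fewer folds or more subjects")
    }
  }
  pred <- matrix(NA_character_, nrow(parts$x), length(algorithms),
                 dimnames = list(NULL, algorithms))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    if (!any(te)) next
    x_tr_raw <- parts$x[tr, , drop = FALSE]
    x_te_raw <- parts$x[te, , drop = FALSE]
    std <- standardizer(x_tr_raw)
    x_tr_std <- apply_standardizer(std, x_tr_raw)
    x_te_std <- apply_standardizer(std, x_te_raw)
    for (algo in algorithms) {
      set.seed(seed * 1000L + f)
      if (.needs_standardization(algo)) {
        m <- .fit_algo(algo, x_tr_std, parts$y[tr], num_trees)
        p <- .predict_algo(m, x_te_std)
      } else {
        m <- .fit_algo(algo, x_tr_raw, parts$y[tr], num_trees)
        p <- .predict_algo(m, x_te_raw)
      }
      pred[te, algo] <- ifelse(p > 0, "PD", "control")
    }
  }
  truth <- as.character(parts$labels)
  metrics <- data.frame(algorithm = algorithms, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_,
                        accuracy = NA_real_, stringsAsFactors = FALSE)
  confusion <- list(); per_fold <- list()
  for (algo in algorithms) {
    mm <- classification_metrics(truth, pred[, algo], average)
    metrics[metrics$algorithm == algo,
            c("precision", "recall", "f1", "accuracy")] <-
      as.list(mm[c("precision", "recall", "f1", "accuracy")])
    confusion[[algo]] <- mm$confusion
    per_fold[[algo]] <- vapply(seq_len(folds), function(f) {
      classification_metrics(truth[fold_id == f],
                             pred[fold_id == f, algo], average)$f1
    }, numeric(1))
  }
  structure(list(metrics = metrics, confusion = confusion,
                 per_fold = per_fold, fold_id = fold_id, folds = folds,
                 seed = seed, average = average, predictions = pred),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> ", x$folds,
      "-fold subject-grouped CV (seed ", x$seed, ")\n", sep = "")
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit a final model on the full feature table
#'
#' The returned artifact stores the feature column order and the
#' standardization parameters, so prediction on a new table aligns columns
#' by name and reproduces in-memory predictions exactly after a
#' `saveRDS()`/`readRDS()` round trip.
#'
#' @param table A [feature_table()].
#' @param algorithm One of `c("lr", "svm", "dt", "rf")`.
#' @param seed Integer seed.
#' @param path Optional path; when given the artifact is `saveRDS()`-ed
#'   there.
#' @param num_trees Trees in the random forest.
#' @return Object of class `facetremor_model`.
#' @export
fit_final <- function(table, algorithm, seed = 1L, path = NULL,
                      num_trees = 100) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  parts <- split_feature_table(table)
  std <- standardizer(parts$x)
  x <- if (.needs_standardization(algorithm)) {
    apply_standardizer(std, parts$x)
  } else {
    parts$x
  }
  set.seed(seed)
  model <- .fit_algo(algorithm, x, parts$y, num_trees)
  art <- structure(list(algorithm = algorithm, model = model,
                        feature_names = colnames(parts$x),
                        standardizer = std, seed = seed),
                   class = "facetremor_model")
  if (!is.null(path)) saveRDS(art, path)
  art
}

#' Predict labels from a fitted model artifact
#'
#' @param object A [fit_final()] artifact.
#' @param table A feature table (metadata columns optional); feature columns
#'   are aligned by name, so column order does not matter.
#' @param ... Unused.
#' @return Character vector of predicted labels (PD/control).
#' @export
predict.facetremor_model <- function(object, table, ...) {
  nm <- object$feature_names
  miss <- setdiff(nm, colnames(table))
  if (length(miss)) {
    stop("prediction table lacks ", length(miss), " feature column(s): ",
         paste(utils::head(miss, 3), collapse = ", "), " ...")
  }
  x <- as.matrix(table[, nm, drop = FALSE])
  if (.needs_standardization(object$algorithm)) {
    x <- apply_standardizer(object$standardizer, x)
  }
  ifelse(.predict_algo(object$model, x) > 0, "PD", "control")
}
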