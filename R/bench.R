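# The classification benchmark: ten-classifier roster with pinned
# hyperparameters, stratified 10-fold cross-validation with per-fold
# standardization, the 60-run grid over {sketch, stroke} x {all176, lit165,
# cog11} x roster, and linear-SVM feature weights.

#' The classifier roster
#'
#' @return Character vector of the ten classifier names.
#' @export
classifier_roster <- function() {
  c("svm_linear", "svm_rbf", "logreg", "knn", "naive_bayes",
    "decision_tree", "random_forest", "adaboost", "gbt", "deep_learning")
}

#' Build a classifier specification
#'
#' Returns the pinned hyperparameters used throughout the benchmark: SVMs at
#' `C = 1.5` with at most 10,000 iterations, logistic regression at
#' `C = 8.0` (newton-cg solver recorded; realized as ridge-penalized
#' likelihood), 7-nearest neighbours, Gaussian naive Bayes with smoothing
#' `1e-9`, tree methods at their documented defaults (100 trees for the
#' forest and the gradient-boosted trees, 50 AdaBoost rounds at learning
#' rate 0.5), and a deep-learning model with 1,000 tanh hidden units,
#' `alpha = 1`, learning rate 0.001 and the Adam solver.
#'
#' @param name One of [classifier_roster()].
#' @return An object of class `classifier_spec` with `name` and
#'   `hyperparameters`.
#' @export
#' @examples
#' make_classifier("knn")$hyperparameters$k
make_classifier <- function(name) {
  roster <- classifier_roster()
  if (!name %in% roster) {
    stop("unknown classifier '", name, "'; roster: ",
         paste(roster, collapse = ", "), call. = FALSE)
  }
  hp <- switch(name,
    svm_linear = list(C = 1.5, max_iter = 10000, kernel = "linear"),
    svm_rbf = list(C = 1.5, max_iter = 10000, kernel = "rbf"),
    logreg = list(C = 8.0, solver = "newton-cg"),
    knn = list(k = 7),
    naive_bayes = list(var_smoothing = 1e-9),
    decision_tree = list(),
    random_forest = list(n_trees = 100),
    adaboost = list(learning_rate = 0.5, n_estimators = 50),
    gbt = list(n_trees = 100, eta = 0.3, max_depth = 6),
    deep_learning = list(hidden_units = 1000, alpha = 1,
                         learning_rate = 0.001, solver = "adam",
                         activation = "tanh", max_iter = 200)
  )
  structure(list(name = name, hyperparameters = hp),
            class = "classifier_spec")
}

# Stratified fold assignment (1..folds), deterministic given the RNG state.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated evaluation of one classifier on one feature table
#'
#' Stratified k-fold cross-validation. Feature standardization (z-scoring)
#' is computed on each training fold only and applied to its test fold, so
#' no test-fold statistics leak into training. Accuracy, macro-averaged
#' precision and recall are averaged over folds with equal weights; F1 is
#' the harmonic mean of the averaged precision and recall; the ROC curve and
#' AUC are computed from the fold-concatenated decision scores.
#'
#' @param table A `feature_table` from [build_feature_table()].
#' @param spec A [make_classifier()] specification.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and stochastic
#'   learners.
#' @param standardize Standardize features per training fold (default TRUE).
#' @return An object of class `metrics_record`: `accuracy`, `precision`,
#'   `recall`, `f1`, `auc_roc` (all in `[0, 1]`) and `roc_points`
#'   (data.frame `fpr`, `tpr` monotone in `fpr`).
#' @export
run_cv <- function(table, spec, folds = 10, seed = 1, standardize = TRUE) {
  fc <- feature_columns(table)
  X <- as.matrix(table[, fc, drop = FALSE])
  storage.mode(X) <- "double"
  y <- factor(table$label, levels = c("healthy", "suspicious"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("both classes must be present in the table", call. = FALSE)
  }
  if (nrow(X) < folds) stop("need at least as many rows as folds",
                            call. = FALSE)
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  acc <- prec <- rec <- numeric(0)
  pooled_score <- numeric(nrow(X))
  pooled_pred <- character(nrow(X))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    fit <- fit_learner(spec, Xtr, y[tr], seed = seed + f)
    pr <- predict_learner(fit, Xte)
    pooled_score[te] <- pr$score
    pooled_pred[te] <- as.character(pr$class)
    acc <- c(acc, mean(pr$class == y[te]))
    pr_cl <- rc_cl <- numeric(0)
    for (cl in levels(y)) {
      tp <- sum(pr$class == cl & y[te] == cl)
      fp <- sum(pr$class == cl & y[te] != cl)
      fn <- sum(pr$class != cl & y[te] == cl)
      if (tp + fn == 0) next  # class absent from this fold
      pr_cl <- c(pr_cl, if (tp + fp > 0) tp / (tp + fp) else 0)
      rc_cl <- c(rc_cl, tp / (tp + fn))
    }
    prec <- c(prec, mean(pr_cl))
    rec <- c(rec, mean(rc_cl))
  }
  precision <- mean(prec); recall <- mean(rec)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  roc <- pROC::roc(response = y, predictor = pooled_score,
                   levels = c("healthy", "suspicious"), direction = "<",
                   quiet = TRUE)
  roc_points <- data.frame(fpr = 1 - roc$specificities,
                           tpr = roc$sensitivities)
  roc_points <- roc_points[order(roc_points$fpr, roc_points$tpr), ]
  structure(list(accuracy = mean(acc), precision = precision,
                 recall = recall, f1 = f1,
                 auc_roc = as.numeric(roc$auc), roc_points = roc_points),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(
    "<metrics_record> acc %.3f  prec %.3f  rec %.3f  F1 %.3f  AUC %.3f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$auc_roc))
  invisible(x)
}

#' Run the full benchmark grid
#'
#' Builds the six feature tables ({sketch, stroke} granularity x {all176,
#' lit165, cog11} subsets) from a labeled cohort and evaluates the whole
#' classifier roster on each by cross-validation: 60 runs in total with the
#' default arguments.
#'
#' @param cohort An `ink_cohort` or list of [labeled_sample()]s.
#' @param seed Integer seed for fold assignment and stochastic learners.
#' @param granularities,subsets,classifiers Grid axes (defaults reproduce
#'   the full 2 x 3 x 10 grid).
#' @param folds CV folds (default 10).
#' @return An object of class `benchmark_grid`: list of runs, each with
#'   `granularity`, `subset_id`, `classifier`, `metrics` and `seed`.
#' @export
run_grid <- function(cohort, seed = 1,
                     granularities = c("sketch", "stroke"),
                     subsets = c("all176", "lit165", "cog11"),
                     classifiers = classifier_roster(), folds = 10) {
  runs <- list()
  for (gr in granularities) {
    for (ss in subsets) {
      table <- build_feature_table(cohort, subset = ss, granularity = gr)
      for (cl in classifiers) {
        spec <- make_classifier(cl)
        metrics <- run_cv(table, spec, folds = folds, seed = seed)
        metrics$roc_points <- NULL  # keep the grid object light
        runs[[length(runs) + 1L]] <- list(
          granularity = gr, subset_id = ss, classifier = spec,
          metrics = metrics, seed = seed)
      }
    }
  }
  structure(runs, class = "benchmark_grid")
}

#' Tabulate a benchmark grid
#'
#' @param grid A `benchmark_grid`.
#' @param top_n Keep the `top_n` most accurate methods per (granularity,
#'   subset) cell; `Inf` keeps everything.
#' @return A `data.frame` with columns `feature_subset`, `method`,
#'   `accuracy`, `precision`, `recall`, `f1`, `auc_roc`, sorted by accuracy
#'   within each subset.
#' @export
grid_report <- function(grid, top_n = 5) {
  df <- do.call(rbind, lapply(grid, function(r) {
    data.frame(
      feature_subset = paste0(
        if (r$granularity == "sketch") "Sketch-" else "Stroke-",
        c(all176 = "176", lit165 = "165", cog11 = "11")[r$subset_id]),
      method = r$classifier$name,
      accuracy = r$metrics$accuracy, precision = r$metrics$precision,
      recall = r$metrics$recall, f1 = r$metrics$f1,
      auc_roc = r$metrics$auc_roc, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(df, df$feature_subset), function(d) {
    d <- d[order(-d$accuracy), ]
    utils::head(d, top_n)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-validated linear-SVM feature weights
#'
#' Trains the linear SVM on every training fold, recovers the primal weight
#' vector, averages absolute weights across folds and returns the `top_k`
#' features by mean absolute weight -- the transparency view of what drives
#' the healthy/suspicious decision.
#'
#' @param table A `feature_table`.
#' @param spec A [make_classifier()] spec with name `svm_linear`.
#' @param top_k Number of features to return (default 10).
#' @param folds,seed,standardize As in [run_cv()].
#' @return `data.frame` with columns `feature` and `mean_abs_weight`,
#'   ranked decreasing, at most `top_k` rows.
#' @export
linear_svm_feature_weights <- function(table, spec = make_classifier("svm_linear"),
                                       top_k = 10, folds = 10, seed = 1,
                                       standardize = TRUE) {
  if (spec$name != "svm_linear") {
    stop("feature weights require the linear SVM", call. = FALSE)
  }
  fc <- feature_columns(table)
  X <- as.matrix(table[, fc, drop = FALSE])
  storage.mode(X) <- "double"
  y <- factor(table$label, levels = c("healthy", "suspicious"))
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  wsum <- rep(0, ncol(X))
  used <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    }
    m <- e1071::svm(Xtr, y[tr], kernel = "linear",
                    cost = spec$hyperparameters$C, scale = FALSE)
    w <- drop(t(m$coefs) %*% m$SV)
    wsum <- wsum + abs(w)
    used <- used + 1L
  }
  out <- data.frame(feature = fc, mean_abs_weight = wsum / used,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_weight), ]
  rownames(out) <- NULL
  utils::head(out, min(top_k, nrow(out)))
}
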