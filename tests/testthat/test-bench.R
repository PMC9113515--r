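# Small synthetic feature tables for classifier tests.
blob_table <- function(n = 200, d = 2, sep = 6, seed = 1, ratio = 0.5) {
  set.seed(seed)
  n1 <- round(n * ratio); n0 <- n - n1
  X <- rbind(matrix(stats::rnorm(n0 * d, 0), n0, d),
             matrix(stats::rnorm(n1 * d, sep), n1, d))
  df <- data.frame(sample_id = sprintf("r%03d", seq_len(n)),
                   stroke_index = -1L,
                   label = rep(c("healthy", "suspicious"), c(n0, n1)),
                   X, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "stroke_index", "label",
                 paste0("f", seq_len(d)))
  attr(df, "subset_id") <- "custom"
  attr(df, "granularity") <- "sketch"
  class(df) <- c("feature_table", "data.frame")
  df
}

test_that("classifier specs carry the pinned hyperparameters", {
  expect_equal(make_classifier("svm_linear")$hyperparameters$C, 1.5)
  expect_equal(make_classifier("svm_linear")$hyperparameters$max_iter, 10000)
  expect_equal(make_classifier("svm_rbf")$hyperparameters$C, 1.5)
  expect_equal(make_classifier("logreg")$hyperparameters$C, 8.0)
  expect_equal(make_classifier("logreg")$hyperparameters$solver, "newton-cg")
  expect_equal(make_classifier("knn")$hyperparameters$k, 7)
  expect_equal(make_classifier("naive_bayes")$hyperparameters$var_smoothing,
               1e-9)
  expect_equal(make_classifier("adaboost")$hyperparameters$learning_rate, 0.5)
  dl <- make_classifier("deep_learning")$hyperparameters
  expect_equal(dl$hidden_units, 1000)
  expect_equal(dl$alpha, 1)
  expect_equal(dl$learning_rate, 0.001)
  expect_equal(dl$solver, "adam")
  expect_equal(dl$activation, "tanh")
  expect_length(classifier_roster(), 10L)
  expect_error(make_classifier("svm_cubic"), "roster")
})

test_that("well-separated blobs are classified perfectly by the linear SVM", {
  tb <- blob_table(n = 200, sep = 8, seed = 2)
  m <- run_cv(tb, make_classifier("svm_linear"), folds = 10, seed = 3)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$auc_roc, 1.0)
})

test_that("pure-noise features recover only the majority baseline", {
  tb <- blob_table(n = 200, sep = 0, seed = 4, ratio = 0.25)  # 150:50
  m <- run_cv(tb, make_classifier("logreg"), folds = 10, seed = 5)
  expect_gte(m$accuracy, 0.70)
  expect_lte(m$accuracy, 0.80)
  # leakage canary: per-fold standardization of noise must not lift AUC far
  # from chance
  expect_lt(abs(m$auc_roc - 0.5), 0.15)
})

test_that("cross-validation tests every row exactly once", {
  tb <- blob_table(n = 236, sep = 3, seed = 6)
  # pooled predictions exist for all rows: reconstruct fold assignment
  y <- factor(tb$label, levels = c("healthy", "suspicious"))
  set.seed(7)
  fold <- inkassess:::stratified_folds(y, 10)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), 236L)
  counts <- table(fold, y)
  expect_true(all(abs(counts[, 1] - mean(counts[, 1])) <= 1))
  expect_true(all(abs(counts[, 2] - mean(counts[, 2])) <= 1))
})

test_that("metrics respect their invariants and rerun identically", {
  tb <- blob_table(n = 120, sep = 2, seed = 8)
  for (nm in c("random_forest", "adaboost", "deep_learning")) {
    m <- run_cv(tb, make_classifier(nm), folds = 5, seed = 9)
    for (f in c("accuracy", "precision", "recall", "f1", "auc_roc")) {
      expect_gte(m[[f]], 0); expect_lte(m[[f]], 1)
    }
    expect_equal(m$f1,
                 2 * m$precision * m$recall / (m$precision + m$recall))
    expect_true(all(diff(m$roc_points$fpr) >= 0))
    m2 <- run_cv(tb, make_classifier(nm), folds = 5, seed = 9)
    expect_identical(m, m2)
  }
  one_class <- blob_table(n = 40, seed = 10)
  one_class$label <- "healthy"
  expect_error(run_cv(one_class, make_classifier("knn")), "both classes")
})

test_that("linear-SVM weights rank an informative feature first", {
  set.seed(11)
  n <- 120
  y <- rep(c("healthy", "suspicious"), each = n / 2)
  X <- cbind(sig = ifelse(y == "suspicious", 3, 0) + stats::rnorm(n, 0, 0.5),
             noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  tb <- data.frame(sample_id = as.character(seq_len(n)), stroke_index = -1L,
                   label = y, X, stringsAsFactors = FALSE)
  class(tb) <- c("feature_table", "data.frame")
  w <- linear_svm_feature_weights(tb, top_k = 10, seed = 12)
  expect_equal(w$feature[1], "sig")
  expect_lte(nrow(w), 10L)
  expect_equal(nrow(linear_svm_feature_weights(tb, top_k = 99, seed = 12)),
               3L)
  expect_error(linear_svm_feature_weights(tb, make_classifier("svm_rbf")),
               "linear")
})

test_that("t-SNE embeds to two dimensions, seeded and cluster-preserving", {
  skip_if_not_installed("cluster")
  set.seed(13)
  X <- rbind(matrix(stats::rnorm(50 * 20, 0), 50),
             matrix(stats::rnorm(50 * 20, 10), 50))
  emb <- tsne_embed(X, seed = 14)
  expect_equal(dim(emb), c(100L, 2L))
  expect_identical(emb, tsne_embed(X, seed = 14))
  sil <- cluster::silhouette(rep(1:2, each = 50), stats::dist(emb))
  expect_gt(mean(sil[, 3]), 0.5)
  # too few rows for the default perplexity: auto-shrink with warning
  expect_warning(small <- tsne_embed(X[1:12, ], seed = 15), "perplexity")
  expect_equal(dim(small), c(12L, 2L))
})

test_that("the grid enumerates granularity x subset x roster and reports", {
  cohort <- generate_cohort(cohort_spec(24, 0.5, seed = 20, tests = "TMT_A"))
  grid <- run_grid(cohort, seed = 21, granularities = "sketch",
                   subsets = c("cog11"), classifiers = c("knn", "logreg"),
                   folds = 5)
  expect_length(grid, 1L * 1L * 2L)
  rep_ <- grid_report(grid, top_n = 5)
  expect_true(all(c("feature_subset", "method", "accuracy") %in% names(rep_)))
  expect_equal(unique(rep_$feature_subset), "Sketch-11")
  grid2 <- run_grid(cohort, seed = 21, granularities = "sketch",
                    subsets = c("cog11"), classifiers = c("knn", "logreg"),
                    folds = 5)
  expect_identical(grid, grid2)
})
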