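# Fit / predict wrappers for the ten-classifier roster. Each fit_* returns
# an object understood by predict_learner(), which yields the predicted
# class and a numeric score for the suspicious class (probability or
# decision value) for ROC analysis.
#
# AdaBoost (SAMME over decision stumps) and the one-hidden-layer tanh MLP
# trained with Adam are implemented here because the benchmark pins their
# hyperparameters explicitly.

.positive_class <- "suspicious"

fit_learner <- function(spec, X, y, seed = 1) {
  hp <- spec$hyperparameters
  set.seed(seed)
  y <- factor(y, levels = c("healthy", "suspicious"))
  model <- switch(spec$name,
    svm_linear = e1071::svm(X, y, kernel = "linear", cost = hp$C,
                            scale = FALSE, probability = FALSE),
    svm_rbf = e1071::svm(X, y, kernel = "radial", cost = hp$C,
                         scale = FALSE, probability = FALSE),
    logreg = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = 1 / (hp$C * nrow(X)),
                            standardize = FALSE),
    knn = list(X = X, y = y, k = hp$k),
    naive_bayes = fit_gnb(X, y, hp$var_smoothing),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(X, y = y), method = "class"),
    random_forest = randomForest::randomForest(X, y, ntree = hp$n_trees),
    adaboost = fit_adaboost(X, y, n_rounds = hp$n_estimators,
                            learning_rate = hp$learning_rate),
    gbt = {
      d <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       eta = hp$eta, max_depth = hp$max_depth,
                                       nthread = 1),
                         data = d, nrounds = hp$n_trees, verbose = 0)
    },
    deep_learning = fit_mlp(X, as.integer(y) - 1L, hidden = hp$hidden_units,
                            alpha = hp$alpha, lr = hp$learning_rate,
                            max_iter = hp$max_iter, seed = seed),
    stop("no fit method for '", spec$name, "'", call. = FALSE)
  )
  structure(list(name = spec$name, model = model, levels = levels(y)),
            class = "ink_learner")
}

predict_learner <- function(fit, X) {
  lv <- fit$levels
  pos <- which(lv == .positive_class)
  out <- switch(fit$name,
    svm_linear = ,
    svm_rbf = {
      p <- stats::predict(fit$model, X, decision.values = TRUE)
      dv <- drop(attr(p, "decision.values"))
      # libsvm orients the decision value toward the first training class
      flip <- grepl(paste0("^", .positive_class, "/"),
                    colnames(attr(p, "decision.values"))[1L])
      list(class = as.character(p), score = if (flip) dv else -dv)
    },
    logreg = {
      pr <- drop(stats::predict(fit$model, X, type = "response"))
      list(class = lv[1L + (pr > 0.5)], score = pr)
    },
    knn = {
      p <- class::knn(fit$model$X, X, fit$model$y, k = fit$model$k,
                      prob = TRUE)
      win <- attr(p, "prob")
      score <- ifelse(as.character(p) == .positive_class, win, 1 - win)
      list(class = as.character(p), score = score)
    },
    naive_bayes = {
      pr <- predict_gnb(fit$model, X)
      list(class = lv[1L + (pr > 0.5)], score = pr)
    },
    decision_tree = {
      pr <- stats::predict(fit$model, data.frame(X), type = "prob")[, pos]
      list(class = lv[1L + (pr > 0.5)], score = pr)
    },
    random_forest = {
      pr <- stats::predict(fit$model, X, type = "prob")[, .positive_class]
      list(class = lv[1L + (pr > 0.5)], score = pr)
    },
    adaboost = {
      m <- predict_adaboost(fit$model, X)
      list(class = lv[1L + (m > 0)], score = m)
    },
    gbt = {
      pr <- stats::predict(fit$model, xgboost::xgb.DMatrix(X))
      list(class = lv[1L + (pr > 0.5)], score = pr)
    },
    deep_learning = {
      pr <- predict_mlp(fit$model, X)
      list(class = lv[1L + (pr > 0.5)], score = pr)
    },
    stop("no predict method for '", fit$name, "'", call. = FALSE)
  )
  out$class <- factor(out$class, levels = lv)
  out
}

# --- Gaussian naive Bayes with an explicit variance floor -------------------

fit_gnb <- function(X, y, var_smoothing = 1e-9) {
  lv <- levels(y)
  glob_var <- max(apply(X, 2, stats::var), 1e-12)
  stats_by <- lapply(lv, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    va <- apply(Xi, 2, stats::var)
    va[!is.finite(va)] <- 0
    va <- va + var_smoothing * glob_var
    va <- pmax(va, 1e-12)
    list(mu = mu, var = va, prior = mean(y == cl))
  })
  names(stats_by) <- lv
  stats_by
}

predict_gnb <- function(model, X) {
  ll <- vapply(model, function(st) {
    rowSums(-0.5 * log(2 * pi * rep(st$var, each = nrow(X))) -
            0.5 * sweep(X, 2, st$mu)^2 /
              rep(st$var, each = nrow(X))) + log(st$prior)
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  m <- apply(ll, 1, max)
  p <- exp(ll - m)
  p[, .positive_class] / rowSums(p)
}

# --- AdaBoost (SAMME) over decision stumps ----------------------------------

fit_adaboost <- function(X, y, n_rounds = 50, learning_rate = 0.5) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(X, y = y)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err <= 0) {
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)  # perfect stump dominates
      break
    }
    if (err >= 0.5) break
    alpha <- learning_rate * log((1 - err) / err)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
  }
  if (length(stumps) == 0L) {
    # no stump beats chance: fall back to the prior margin
    return(list(stumps = list(), alphas = numeric(0),
                prior = mean(y == .positive_class) - 0.5))
  }
  list(stumps = stumps, alphas = alphas, prior = 0)
}

predict_adaboost <- function(model, X) {
  if (length(model$stumps) == 0L) return(rep(model$prior, nrow(X)))
  df <- data.frame(X)
  margin <- rep(0, nrow(X))
  for (m in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[m]], df, type = "class")
    margin <- margin + model$alphas[m] *
      ifelse(as.character(pred) == .positive_class, 1, -1)
  }
  margin
}

# --- one-hidden-layer tanh MLP trained with Adam ----------------------------

fit_mlp <- function(X, y01, hidden = 1000, alpha = 1, lr = 0.001,
                    max_iter = 200, seed = 1, tol = 1e-5,
                    n_iter_no_change = 10) {
  set.seed(seed)
  n <- nrow(X); d <- ncol(X)
  W1 <- matrix(stats::rnorm(d * hidden, 0, sqrt(1 / d)), d, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(stats::rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1)
  b2 <- 0
  mW1 <- vW1 <- matrix(0, d, hidden); mb1 <- vb1 <- rep(0, hidden)
  mW2 <- vW2 <- matrix(0, hidden, 1); mb2 <- vb2 <- 0
  b1_ <- 0.9; b2_ <- 0.999; eps <- 1e-8
  best <- Inf; stall <- 0L
  for (it in seq_len(max_iter)) {
    Z <- tanh(sweep(X %*% W1, 2, b1, "+"))
    s <- drop(Z %*% W2) + b2
    p <- 1 / (1 + exp(-s))
    loss <- -mean(y01 * log(pmax(p, 1e-12)) +
                  (1 - y01) * log(pmax(1 - p, 1e-12))) +
      0.5 * alpha * (sum(W1^2) + sum(W2^2)) / n
    if (loss < best - tol) { best <- loss; stall <- 0L } else {
      stall <- stall + 1L
      if (stall >= n_iter_no_change) break
    }
    ds <- matrix((p - y01) / n, ncol = 1)
    gW2 <- t(Z) %*% ds + alpha * W2 / n
    gb2 <- sum(ds)
    dZ <- (ds %*% t(W2)) * (1 - Z^2)
    gW1 <- t(X) %*% dZ + alpha * W1 / n
    gb1 <- colSums(dZ)
    upd <- function(m, v, g) {
      m <- b1_ * m + (1 - b1_) * g
      v <- b2_ * v + (1 - b2_) * g^2
      mh <- m / (1 - b1_^it); vh <- v / (1 - b2_^it)
      list(m = m, v = v, step = lr * mh / (sqrt(vh) + eps))
    }
    u <- upd(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$step
    u <- upd(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$step
    u <- upd(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$step
    u <- upd(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$step
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

predict_mlp <- function(model, X) {
  Z <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  drop(1 / (1 + exp(-(Z %*% model$W2 + model$b2))))
}
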