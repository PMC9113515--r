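# Exact t-distributed stochastic neighbour embedding (no tree
# approximation; the feature tables this package embeds hold at most a few
# thousand rows, where the O(n^2) exact gradient is fast and reproducible).

# Conditional probabilities with per-point precision tuned by binary search
# to the target perplexity.
tsne_affinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP <= 0) sumP <- .Machine$double.eps
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P
}

#' Two-dimensional t-SNE embedding of a feature table
#'
#' Maps the high-dimensional feature vectors to the plane for visualising
#' class structure and decision boundaries. Defaults are the standard
#' visualisation settings: 2 components, perplexity 30, early exaggeration
#' 12.0, learning rate 200.0 and at most 1,000 iterations. When the table
#' has too few rows for the requested perplexity (it must be at most
#' `(n - 1) / 3`), the perplexity is shrunk automatically with a warning.
#'
#' @param table A `feature_table` or numeric matrix (rows = samples).
#' @param seed Integer seed; embeddings are deterministic given it.
#' @param perplexity,early_exaggeration,learning_rate,max_iter t-SNE
#'   parameters.
#' @return Numeric matrix (n x 2) with columns `V1`, `V2`; attribute
#'   `labels` carries the table's labels when present.
#' @export
tsne_embed <- function(table, seed = 1, perplexity = 30,
                       early_exaggeration = 12, learning_rate = 200,
                       max_iter = 1000) {
  labels <- NULL
  if (inherits(table, "feature_table") || is.data.frame(table)) {
    labels <- table$label
    X <- as.matrix(table[, feature_columns(table), drop = FALSE])
  } else {
    X <- as.matrix(table)
  }
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to embed", call. = FALSE)
  max_perp <- max(1, floor((n - 1) / 3))
  if (perplexity > max_perp) {
    warning(sprintf("perplexity %g too large for %d rows; shrunk to %d",
                    perplexity, n, max_perp), call. = FALSE)
    perplexity <- max_perp
  }
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (it in seq_len(max_iter)) {
    Pit <- if (it <= 250) P * early_exaggeration else P
    momentum <- if (it <= 250) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    L <- (Pit - Q) * num
    G <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    gains <- ifelse(sign(G) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - learning_rate * gains * G
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- c("V1", "V2")
  attr(Y, "labels") <- labels
  Y
}

#' Plot a labeled 2-D embedding
#'
#' Scatter plot of a [tsne_embed()] result with the conventional class
#' colours (red = healthy, blue = suspicious).
#'
#' @param emb Matrix from [tsne_embed()].
#' @param labels Optional label vector (defaults to the embedding's
#'   attribute).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `emb`.
#' @export
plot_embedding <- function(emb, labels = attr(emb, "labels"), ...) {
  col <- if (is.null(labels)) "grey30" else
    ifelse(labels == "suspicious", "blue", "red")
  graphics::plot(emb[, 1], emb[, 2], col = col, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  if (!is.null(labels)) {
    graphics::legend("topright", legend = c("healthy", "suspicious"),
                     col = c("red", "blue"), pch = 19, bty = "n")
  }
  invisible(emb)
}
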