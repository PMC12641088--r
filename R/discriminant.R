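#' Gaussian linear discriminant analysis: fit and predict
#'
#' Classical LDA with a pooled within-class covariance and (by default)
#' empirical class priors: a test point is assigned to the class k
#' maximising the linear discriminant score
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log(prior_k)`.
#' If the pooled covariance is singular a ridge of
#' `1e-8 * trace(S) / g` is added once (with a message); if it is still
#' singular the fit errors.
#'
#' @param train_x numeric matrix (rows = samples) or vector (1 feature).
#' @param train_y class labels (>= 2 classes present).
#' @param test_x matrix/vector of points to classify.
#' @param prior "empirical" (class frequencies, default) or "uniform".
#' @return character vector of predicted class labels for `test_x`.
#' @export
lda_fit_predict <- function(train_x, train_y, test_x,
                            prior = c("empirical", "uniform")) {
  prior <- match.arg(prior)
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  storage.mode(train_x) <- storage.mode(test_x) <- "double"
  y <- factor(train_y)
  g <- nlevels(y)
  if (g < 2L) abort("need >= 2 classes in the training labels")
  n <- nrow(train_x)
  d <- ncol(train_x)
  stopifnot(length(train_y) == n, ncol(test_x) == d)
  mus <- matrix(NA_real_, g, d)
  for (k in seq_len(g)) {
    mus[k, ] <- colMeans(train_x[y == levels(y)[k], , drop = FALSE])
  }
  pooled <- matrix(0, d, d)
  for (k in levels(y)) {
    xk <- train_x[y == k, , drop = FALSE]
    centered <- sweep(xk, 2, colMeans(xk))
    pooled <- pooled + crossprod(centered)
  }
  pooled <- pooled / (n - g)
  if (sum(diag(pooled)) <= 0) {
    abort("pooled within-class covariance is singular (constant features)")
  }
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(inv)) {
    pooled <- pooled + diag(1e-8 * sum(diag(pooled)) / g, d)
    inv <- tryCatch(solve(pooled), error = function(e) NULL)
    if (is.null(inv)) abort("pooled covariance singular even after ridge")
    message("ridge regularization applied to the pooled covariance")
  }
  pk <- if (prior == "empirical") as.vector(table(y)) / n else rep(1 / g, g)
  # score matrix: n_test x g
  lin <- test_x %*% inv %*% t(mus)
  const <- -0.5 * rowSums((mus %*% inv) * mus) + log(pk)
  scores <- sweep(lin, 2, const, `+`)
  levels(y)[max.col(scores, ties.method = "first")]
}

#' Leave-one-out hit rate of an LDA model
#'
#' For each sample, fits the discriminant on all other samples and
#' predicts the held-out one; assembles the hit rate, the confusion
#' matrix (rows = true class, columns = predicted class) and per-class
#' hit fractions over all N folds. A fold whose training set loses a
#' class entirely predicts over the remaining classes and is noted in
#' `degenerate_folds`.
#'
#' @inheritParams lda_fit_predict
#' @param x feature matrix or vector.
#' @param y class labels.
#' @return object of class `discriminant_result`: `feature_set` (column
#'   names), `hit_rate`, `confusion`, `per_class_hit`, `predicted`,
#'   `n`, `degenerate_folds`.
#' @export
loo_hit_rate <- function(x, y, prior = c("empirical", "uniform")) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  if (n < nlevels(y) + 2L) abort("need N >= number of classes + 2")
  predicted <- character(n)
  degenerate <- integer(0)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(y)) degenerate <- c(degenerate, i)
    predicted[i] <- lda_fit_predict(x[-i, , drop = FALSE], ytr,
                                    x[i, , drop = FALSE], prior = prior)
  }
  if (length(degenerate)) {
    message("folds with a class absent from training: ",
            paste(degenerate, collapse = ", "))
  }
  confusion <- table(true = y, predicted = factor(predicted,
                                                  levels = levels(y)))
  structure(list(
    feature_set = colnames(x),
    hit_rate = sum(diag(confusion)) / n,
    confusion = unclass(confusion),
    per_class_hit = diag(confusion) / rowSums(confusion),
    predicted = predicted, n = n,
    degenerate_folds = degenerate), class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf("LOO-LDA [%s]: hit rate %.3f (n = %d)\n",
              paste(x$feature_set, collapse = " + "), x$hit_rate, x$n))
  print(x$confusion)
  invisible(x)
}

#' Exhaustive leave-one-out LDA search over regions and region pairs
#'
#' Evaluates a leave-one-out LDA of cluster membership on the CBF of
#' every single territory and (when `max_size = 2`) of every unordered
#' territory pair — 24 + 276 = 300 models for the full 24-region table.
#' Models are ranked by hit rate; ties break lexicographically on the
#' canonical region ordering so "the best model" is reproducible.
#'
#' @param cbf a `cbf_table` or participant x region matrix.
#' @param labels cluster per participant (named vector or aligned).
#' @param max_size 1 (singles only) or 2 (singles + pairs).
#' @param prior passed to [lda_fit_predict()].
#' @return list of class `discriminant_search`: `ranking` (data.frame
#'   feature_set / size / hit_rate, ranked), `results` (named list of
#'   `discriminant_result`), `best` (top result), `best_single`,
#'   `pair_beats_single` (logical, NA when pairs were not searched).
#' @export
exhaustive_search <- function(cbf, labels, max_size = 2L,
                              prior = c("empirical", "uniform")) {
  prior <- match.arg(prior)
  stopifnot(max_size %in% 1:2)
  mat <- if (is.matrix(cbf)) cbf else cbf_matrix(cbf, complete = TRUE)
  if (!is.null(names(labels))) labels <- labels[rownames(mat)]
  stopifnot(length(labels) == nrow(mat))
  regions <- colnames(mat)
  sets <- lapply(regions, identity)
  if (max_size == 2L) {
    pair_idx <- utils::combn(length(regions), 2L)
    sets <- c(sets, lapply(seq_len(ncol(pair_idx)), function(p) {
      regions[pair_idx[, p]]
    }))
  }
  results <- lapply(sets, function(fs) {
    loo_hit_rate(mat[, fs, drop = FALSE], labels, prior = prior)
  })
  names(results) <- vapply(sets, paste, "", collapse = "+")
  ranking <- data.frame(
    feature_set = names(results),
    size = lengths(sets),
    hit_rate = vapply(results, `[[`, 0, "hit_rate"),
    row.names = NULL)
  ord <- order(-ranking$hit_rate, seq_len(nrow(ranking)))  # ties: canonical order
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  best_single_name <- ranking$feature_set[ranking$size == 1L][1L]
  out <- list(ranking = ranking,
              results = results,
              best = results[[ranking$feature_set[1L]]],
              best_single = results[[best_single_name]],
              pair_beats_single = NA)
  if (max_size == 2L) {
    best_pair_rate <- max(ranking$hit_rate[ranking$size == 2L])
    out$pair_beats_single <- best_pair_rate > out$best_single$hit_rate
  }
  class(out) <- "discriminant_search"
  out
}

#' @export
print.discriminant_search <- function(x, ...) {
  cat(sprintf("exhaustive LOO-LDA search: %d models\n", nrow(x$ranking)))
  cat(sprintf("best: [%s] hit rate %.3f\n",
              paste(x$best$feature_set, collapse = " + "), x$best$hit_rate))
  if (!is.na(x$pair_beats_single)) {
    cat("pair exceeds best single region:",
        if (x$pair_beats_single) "yes" else "no", "\n")
  }
  invisible(x)
}
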