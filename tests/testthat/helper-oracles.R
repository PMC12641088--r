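# Independent brute-force oracles used across the suite. These stay
# deliberately naive: loops and first-principles formulas, never the
# package's own computational path.

# dense grid search for the pivotal slope: minimize SS(k) over k
oracle_pivotal_slope <- function(x, y, step = 1e-4) {
  ks <- seq(-5, 5, by = step)
  ss <- vapply(ks, function(k) sum((y - (k * (x - 5) + 5))^2), 0)
  ks[which.min(ss)]
}

# per-point silhouette by explicit pairwise loops
oracle_silhouette <- function(pts, labels) {
  n <- nrow(pts)
  d <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  vapply(seq_len(n), function(i) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) return(0)
    a <- mean(vapply(same, function(j) d(i, j), 0))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(vapply(which(labels == g), function(j) d(i, j), 0))
    }, 0))
    (b - a) / max(a, b)
  }, 0)
}

# classical one-way ANOVA from explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(tapply(values, groups, function(v) {
    sum((v - mean(v))^2)
  }))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# Tukey-Kramer adjusted p for one pair, from the studentized range
oracle_tukey_pair <- function(values, groups, g1, g2) {
  groups <- factor(groups)
  g <- nlevels(groups)
  mse <- oracle_anova(values, groups)
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_w <- length(values) - g
  msw <- ss_within / df_w
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  diff <- mean(values[groups == g1]) - mean(values[groups == g2])
  q <- abs(diff) / sqrt(msw / 2 * (1 / n1 + 1 / n2))
  stats::ptukey(q, g, df_w, lower.tail = FALSE)
}

# leave-one-out LDA by an explicit per-fold refit with MASS
oracle_loo_predictions <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  vapply(seq_len(nrow(x)), function(i) {
    fit <- MASS::lda(x[-i, , drop = FALSE], grouping = droplevels(y[-i]))
    as.character(stats::predict(fit, x[i, , drop = FALSE])$class)
  }, "")
}

# pair-counting agreement (Rand index machinery) by explicit loops
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- sa <- sb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    if (same_a) sa <- sa + 1
    if (same_b) sb <- sb + 1
  }
  np <- n * (n - 1) / 2
  expected <- sa * sb / np
  (s11 - expected) / ((sa + sb) / 2 - expected)
}

# two tight, well-separated Gaussian blobs in the plane
make_blobs <- function(centers, n_each, sd, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    cbind(rnorm(n_each, centers[k, 1], sd), rnorm(n_each, centers[k, 2], sd))
  }))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = n_each))
}
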