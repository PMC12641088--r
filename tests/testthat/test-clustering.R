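test_that("Mahalanobis radius matches chi-square quantiles", {
  expect_equal(round(mahalanobis_radius(0.95, 2), 2), 2.45)
  expect_equal(mahalanobis_radius(0.95, 2), 2.4477, tolerance = 1e-4)
  # 1-D case collapses to the normal quantile
  expect_equal(mahalanobis_radius(0.95, 1), qnorm(0.975), tolerance = 1e-9)
  # independent bisection on the chi-square CDF
  bisect <- function(conf, df) {
    lo <- 0; hi <- 100
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (pchisq(mid, df) < conf) lo <- mid else hi <- mid
    }
    sqrt(mid)
  }
  expect_equal(mahalanobis_radius(0.99, 2), bisect(0.99, 2), tolerance = 1e-6)
  expect_error(mahalanobis_radius(1, 2), "probability")
})

test_that("GMM separates well-separated blobs exactly and is reproducible", {
  b <- make_blobs(rbind(c(1, 1), c(0.2, 0.2)), n_each = 20, sd = 0.02)
  fit <- fit_gmm(b$points, K = 2, seed = 1)
  expect_equal(adjusted_rand_index(fit$labels, b$labels), 1)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # covariances symmetric positive definite
  for (S in fit$covs) {
    expect_equal(S, t(S))
    expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  }
  fit2 <- fit_gmm(b$points, K = 2, seed = 1)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$labels, fit2$labels)
})

test_that("single-component fit has closed-form mean and ML covariance", {
  set.seed(5)
  x <- cbind(rnorm(30), rnorm(30, 2, 0.5))
  fit <- fit_gmm(x, K = 1)
  expect_equal(as.vector(fit$means), colMeans(x))
  expect_equal(fit$covs[[1]], cov(x) * 29 / 30, tolerance = 1e-12)
  expect_error(fit_gmm(x[1:4, ], K = 4), "at most")
})

test_that("mean silhouette equals the pairwise brute-force oracle", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(2, 2), c(2.1, 2), c(1, 1.2))
  labels <- c(1, 1, 1, 2, 2, 2)
  expect_equal(mean_silhouette(pts, labels),
               mean(oracle_silhouette(pts, labels)))
  set.seed(7)
  for (rep in 1:4) {
    p <- matrix(rnorm(24), ncol = 2)
    l <- sample(1:3, 12, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(mean_silhouette(p, l), mean(oracle_silhouette(p, l)))
  }
})

test_that("silhouette agrees with the cluster package on random data", {
  set.seed(9)
  p <- matrix(rnorm(60), ncol = 2)
  l <- sample(1:3, 30, replace = TRUE)
  ours <- mean_silhouette(p, l)
  ref <- mean(cluster::silhouette(l, dist(p))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("silhouette conventions: singletons score 0, one cluster errors", {
  pts <- matrix(rnorm(10), ncol = 2)
  expect_equal(mean_silhouette(pts, 1:5), 0)  # all singletons
  expect_error(mean_silhouette(pts, rep(1, 5)), "2 clusters")
  # two tight distant blobs approach the separation limit
  b <- make_blobs(rbind(c(0, 0), c(5, 5)), n_each = 10, sd = 0.01)
  expect_gt(mean_silhouette(b$points, b$labels), 0.9)
})

test_that("mean silhouette is invariant to label permutation", {
  b <- make_blobs(rbind(c(0, 0), c(1, 1), c(2, 0)), n_each = 8, sd = 0.1)
  relabeled <- c(3, 1, 2)[b$labels]
  expect_equal(mean_silhouette(b$points, b$labels),
               mean_silhouette(b$points, relabeled))
})

test_that("silhouette selection recovers three separated blobs", {
  b <- make_blobs(rbind(c(1, 1), c(2.2, 0.8), c(0.3, 0.1)),
                  n_each = 12, sd = 0.07, seed = 3)
  sel <- select_cluster_count(b$points, k_range = 2:6, seed = 1,
                              n_restarts = 15)
  expect_equal(sel$best_k, 3)
  expect_equal(adjusted_rand_index(sel$model$labels, b$labels), 1)
  expect_equal(nrow(sel$trace), 5)
  expect_error(select_cluster_count(b$points, integer(0)), "empty")
})

test_that("silhouette trace equals brute-force recomputation at n = 12", {
  b <- make_blobs(rbind(c(0, 0), c(1.5, 1.5)), n_each = 6, sd = 0.3, seed = 4)
  sel <- select_cluster_count(b$points, k_range = 2:4, seed = 2,
                              n_restarts = 15)
  for (i in seq_len(nrow(sel$trace))) {
    K <- sel$trace$K[i]
    fit <- fit_gmm(b$points, K, seed = 2, n_restarts = 15)
    if (length(unique(fit$labels)) >= 2) {
      expect_equal(sel$trace$mean_silhouette[i],
                   mean(oracle_silhouette(b$points, fit$labels)))
    }
  }
})

test_that("GMM partition agrees with mclust on separated data", {
  suppressPackageStartupMessages(library(mclust))
  b <- make_blobs(rbind(c(1, 0.9), c(2.3, 0.8), c(0.2, 0.1)),
                  n_each = 15, sd = 0.08, seed = 6)
  fit <- fit_gmm(b$points, K = 3, seed = 1)
  mc <- Mclust(b$points, G = 3, modelNames = "VVV", verbose = FALSE)
  expect_equal(adjusted_rand_index(fit$labels, mc$classification), 1)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("confidence ellipses have the right geometry", {
  model <- structure(list(K = 2L,
                          means = rbind(c(0, 0), c(10, 10)),
                          covs = list(diag(2), diag(c(4, 1))),
                          weights = c(0.5, 0.5)),
                     class = "gmm_fit")
  ce <- confidence_ellipses(model, 0.95)
  e1 <- ce$ellipses[[1]]
  # identity covariance: a circle of the Mahalanobis radius
  pts <- ellipse_points(e1)
  expect_equal(sqrt(rowSums(pts^2)), rep(mahalanobis_radius(0.95, 2), 181),
               tolerance = 1e-9)
  # diagonal covariance (4, 1): semi-axes in ratio 2:1
  e2 <- ce$ellipses[[2]]
  p2 <- sweep(ellipse_points(e2), 2, e2$center)
  expect_equal(max(abs(p2[, 1])) / max(abs(p2[, 2])), 2, tolerance = 1e-6)
  # distant ellipses do not overlap
  expect_equal(ce$overlap$overlap_fraction, 0)
})

test_that("ellipse overlap: identical -> 1; grid matches Monte Carlo", {
  model <- structure(list(K = 2L,
                          means = rbind(c(0, 0), c(0, 0)),
                          covs = list(diag(2), diag(2)),
                          weights = c(0.5, 0.5)),
                     class = "gmm_fit")
  ce <- confidence_ellipses(model, 0.95)
  expect_equal(ce$overlap$overlap_fraction, 1)

  model2 <- structure(list(K = 2L,
                           means = rbind(c(0, 0), c(1.5, 0.5)),
                           covs = list(diag(2), diag(c(2, 0.5))),
                           weights = c(0.5, 0.5)),
                      class = "gmm_fit")
  ce2 <- confidence_ellipses(model2, 0.95, grid_n = 401L)
  # Monte Carlo oracle on the joint bounding box
  set.seed(8)
  r <- mahalanobis_radius(0.95, 2)
  lo <- c(-r * sqrt(2), -r * sqrt(2))
  hi <- c(1.5 + r * sqrt(2), 0.5 + r)
  u <- cbind(runif(2e5, lo[1], hi[1]), runif(2e5, lo[2], hi[2]))
  in1 <- mahalanobis(u, c(0, 0), diag(2)) <= r^2
  in2 <- mahalanobis(u, c(1.5, 0.5), diag(c(2, 0.5))) <= r^2
  mc <- sum(in1 & in2) / sum(in1 | in2)
  expect_equal(ce2$overlap$overlap_fraction, mc, tolerance = 0.01)
})
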