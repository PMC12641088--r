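#' Mahalanobis radius of a multivariate normal confidence region
#'
#' The contour enclosing a given probability mass of a d-dimensional
#' Gaussian lies at Mahalanobis distance `sqrt(qchisq(confidence, d))`
#' from its center; in two dimensions the 95% region sits at radius
#' 2.447.
#'
#' @param confidence coverage probability in (0, 1).
#' @param dim dimensionality (positive integer).
#' @return the Mahalanobis radius (dimensionless).
#' @examples
#' mahalanobis_radius(0.95, 2)  # 2.447
#' @export
mahalanobis_radius <- function(confidence, dim = 2L) {
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    abort("confidence must be a single probability in (0, 1)")
  }
  stopifnot(dim >= 1)
  sqrt(stats::qchisq(confidence, df = dim))
}

# log-density of N(mu, sigma) at the rows of x (n x d), via Cholesky
dmvnorm_log <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  centered <- sweep(x, 2, mu)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# add as much ridge as needed (escalating from `ridge`) for a valid
# Cholesky; keeps EM alive on near-duplicate points
floor_cov <- function(sigma, ridge) {
  d <- nrow(sigma)
  for (i in 0:8) {
    s <- sigma + diag(ridge * 10^i, d)
    if (!is.null(tryCatch(chol(s), error = function(e) NULL))) return(s)
  }
  NULL
}

em_once <- function(x, K, tol, max_iter, ridge) {
  n <- nrow(x)
  d <- ncol(x)
  # k-means initial partition (one random start per restart); random-point
  # init is prone to spiky degenerate optima on near-duplicate data
  km <- tryCatch(suppressWarnings(
    stats::kmeans(x, centers = K, nstart = 1, iter.max = 25)),
    error = function(e) NULL)
  init_lab <- if (is.null(km) || length(unique(km$cluster)) < K) {
    # fall back to a random partition seeded from K distinct points
    max.col(-as.matrix(stats::dist(rbind(x[sample.int(n, K), , drop = FALSE],
                                         x)))[-(1:K), 1:K, drop = FALSE])
  } else {
    km$cluster
  }
  base_cov <- floor_cov(stats::cov(x) * (n - 1) / n, ridge)
  if (is.null(base_cov)) return(NULL)
  means <- matrix(NA_real_, K, d)
  covs <- vector("list", K)
  weights <- numeric(K)
  for (k in seq_len(K)) {
    xk <- x[init_lab == k, , drop = FALSE]
    means[k, ] <- colMeans(xk)
    covs[[k]] <- if (nrow(xk) > d) {
      s <- floor_cov(stats::cov(xk) * (nrow(xk) - 1) / nrow(xk), ridge)
      if (is.null(s)) base_cov else s
    } else {
      base_cov
    }
    weights[k] <- nrow(xk) / n
  }
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logdens <- matrix(NA_real_, n, K)
    for (k in seq_len(K)) {
      ld <- dmvnorm_log(x, means[k, ], covs[[k]])
      if (is.null(ld)) return(NULL)
      logdens[, k] <- ld + log(weights[k])
    }
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    if (any(nk < 0.5)) return(NULL)  # effectively empty component
    weights <- nk / n
    for (k in seq_len(K)) {
      mu <- colSums(resp[, k] * x) / nk[k]
      centered <- sweep(x, 2, mu)
      sigma <- floor_cov(crossprod(centered * sqrt(resp[, k])) / nk[k], ridge)
      if (is.null(sigma)) return(NULL)
      means[k, ] <- mu
      covs[[k]] <- sigma
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  # a component collapsed onto the covariance floor is a degenerate
  # (vanishing-covariance) solution: reject the restart
  min_eig <- vapply(covs, function(s) min(eigen(s, symmetric = TRUE,
                                                only.values = TRUE)$values), 0)
  if (any(min_eig < 100 * ridge)) return(NULL)
  list(means = means, covs = covs, weights = weights, loglik = ll,
       resp = resp, iterations = iter)
}

#' Fit a Gaussian mixture model by seeded, restarted EM
#'
#' Full (per-component, unconstrained) covariances; each restart draws
#' fresh initial means from the data points, runs EM to a log-likelihood
#' tolerance, and the restart with the highest final log-likelihood
#' wins. Hard labels are the maximum-posterior component. The fit is
#' deterministic given `(points, K, seed, n_restarts)`. Restarts whose
#' EM degenerates (a component collapsing onto a point) are discarded;
#' an error is raised only if every restart degenerates.
#'
#' @param points numeric matrix or data.frame, rows = observations
#'   (for the response analysis: columns slope and d.c.).
#' @param K number of mixture components (>= 1, <= n - 1).
#' @param seed integer seed controlling the restarts.
#' @param n_restarts number of EM restarts (default 50).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap per restart (default 500).
#' @return object of class `gmm_fit`: `K`, `means` (K x d), `covs`
#'   (list of d x d), `weights`, `labels` (1..K), `posterior` (n x K),
#'   `loglik`, `mean_silhouette` (NA for K = 1 or collapsed labels),
#'   `silhouette` (per point), `seed`.
#' @export
fit_gmm <- function(points, K, seed = 1L, n_restarts = 50L,
                    tol = 1e-6, max_iter = 500L) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) abort("points must be finite")
  n <- nrow(x)
  stopifnot(K >= 1)
  if (K > n - 1) abort("K must be at most n - 1 (got K = ", K, ", n = ", n, ")")
  # covariance floor: keeps components on near-duplicate points proper
  ridge <- 1e-6 * mean(diag(stats::cov(x))) + 1e-12
  if (K == 1L) {
    mu <- colMeans(x)
    sigma <- stats::cov(x) * (n - 1) / n
    best <- list(means = matrix(mu, 1), covs = list(sigma),
                 weights = 1, loglik = sum(dmvnorm_log(x, mu, sigma)),
                 resp = matrix(1, n, 1))
  } else {
    best <- with_seed(seed, {
      b <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- em_once(x, K, tol, max_iter, ridge)
        if (!is.null(fit) && (is.null(b) || fit$loglik > b$loglik)) b <- fit
      }
      b
    })
    if (is.null(best)) abort("EM degenerated in all ", n_restarts, " restarts")
  }
  labels <- max.col(best$resp, ties.method = "first")
  sil <- if (length(unique(labels)) >= 2L) {
    silhouette_values(x, labels)
  } else {
    rep(NA_real_, n)
  }
  structure(list(
    K = as.integer(K), means = best$means, covs = best$covs,
    weights = best$weights, labels = labels, posterior = best$resp,
    loglik = best$loglik,
    mean_silhouette = if (all(is.na(sil))) NA_real_ else mean(sil),
    silhouette = sil, seed = as.integer(seed)),
    class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, log-lik %.2f, mean silhouette %s\n",
              x$K, x$loglik,
              if (is.na(x$mean_silhouette)) "NA"
              else sprintf("%.3f", x$mean_silhouette)))
  cat("cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  invisible(x)
}

# per-point silhouette widths, Euclidean distance
silhouette_values <- function(x, labels) {
  n <- nrow(x)
  dmat <- as.matrix(stats::dist(x))
  uniq <- sort(unique(labels))
  if (length(uniq) < 2L) abort("silhouette requires at least 2 clusters")
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)  # singleton convention
    a <- sum(dmat[i, own]) / (sum(own) - 1L)
    b <- min(vapply(uniq[uniq != labels[i]], function(g) {
      mean(dmat[i, labels == g])
    }, 0))
    (b - a) / max(a, b)
  }, 0)
}

#' Mean silhouette value of a hard clustering
#'
#' For each point, `s = (b - a) / max(a, b)` where a is the mean
#' Euclidean distance to the point's own cluster and b the smallest
#' mean distance to another cluster; singleton-cluster points score 0 by
#' convention. The mean over points reaches 1 only for perfectly
#' compact, separated clusters.
#'
#' @param points numeric matrix/data.frame of observations.
#' @param labels cluster assignment per row (>= 2 distinct values).
#' @return mean silhouette in \[-1, 1\].
#' @export
mean_silhouette <- function(points, labels) {
  x <- as.matrix(points)
  stopifnot(nrow(x) == length(labels))
  mean(silhouette_values(x, labels))
}

#' Select the number of clusters by mean silhouette
#'
#' Fits a Gaussian mixture for every K in `k_range` and keeps the K
#' whose hard labels maximise the mean silhouette — the study's
#' objective criterion for the number of response-pattern clusters.
#' Ties break toward smaller K (parsimony). A fit whose hard labels
#' collapse below two non-empty clusters gets silhouette NA and cannot
#' be selected.
#'
#' @inheritParams fit_gmm
#' @param k_range integer candidates, a subset of 2..(n-1); default 2:6.
#' @return list: `best_k`, `model` (the winning `gmm_fit`), and `trace`
#'   (data.frame K / mean_silhouette / loglik).
#' @export
select_cluster_count <- function(points, k_range = 2:6, seed = 1L,
                                 n_restarts = 50L) {
  if (!length(k_range)) abort("k_range is empty")
  n <- nrow(as.matrix(points))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    abort("k_range must lie within [2, n - 1]")
  }
  # a K whose every EM restart degenerates is infeasible, not fatal
  fits <- lapply(k_range, function(K) {
    tryCatch(fit_gmm(points, K, seed = seed, n_restarts = n_restarts),
             error = function(e) NULL)
  })
  sil <- vapply(fits, function(f) {
    if (is.null(f)) NA_real_ else f$mean_silhouette
  }, 0)
  if (all(is.na(sil))) abort("no candidate K produced a valid clustering")
  best <- which(sil == max(sil, na.rm = TRUE))[1L]  # ties -> smaller K
  list(best_k = k_range[best], model = fits[[best]],
       trace = data.frame(K = k_range, mean_silhouette = sil,
                          loglik = vapply(fits, function(f) {
                            if (is.null(f)) NA_real_ else f$loglik
                          }, 0)))
}

#' Confidence ellipses of a fitted mixture
#'
#' One ellipse per component: the contour at Mahalanobis radius
#' `mahalanobis_radius(confidence, 2)` of the component Gaussian — at
#' the default 95% the radius is 2.447. Also reports the pairwise
#' overlap of the ellipse interiors (intersection area over union area,
#' by grid integration) to quantify how well the clusters separate.
#'
#' @param model a `gmm_fit` on two-dimensional data.
#' @param confidence coverage probability (default 0.95).
#' @param grid_n grid resolution per axis for the overlap integration.
#' @return list: `ellipses` (per component: `center`, `covariance`,
#'   `radius`, `confidence`, `area`) and `overlap` (data.frame i / j /
#'   overlap_fraction).
#' @export
confidence_ellipses <- function(model, confidence = 0.95, grid_n = 201L) {
  stopifnot(inherits(model, "gmm_fit"), ncol(model$means) == 2L)
  r <- mahalanobis_radius(confidence, 2L)
  ellipses <- lapply(seq_len(model$K), function(k) {
    sigma <- model$covs[[k]]
    list(center = model$means[k, ], covariance = sigma, radius = r,
         confidence = confidence,
         area = pi * r^2 * sqrt(max(det(sigma), 0)))
  })
  pairs <- if (model$K >= 2L) utils::combn(model$K, 2L) else NULL
  overlap <- if (is.null(pairs)) {
    data.frame(i = integer(), j = integer(), overlap_fraction = numeric())
  } else {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      data.frame(i = i, j = j,
                 overlap_fraction = ellipse_overlap(ellipses[[i]],
                                                    ellipses[[j]], grid_n))
    }))
  }
  list(ellipses = ellipses, overlap = overlap)
}

# Jaccard overlap (intersection / union) of two ellipse interiors by
# membership counting on a regular grid spanning the joint bounding box.
ellipse_overlap <- function(e1, e2, grid_n = 201L) {
  box <- function(e) {
    half <- e$radius * sqrt(diag(e$covariance))
    rbind(e$center - half, e$center + half)
  }
  b <- rbind(box(e1), box(e2))
  xs <- seq(min(b[, 1]), max(b[, 1]), length.out = grid_n)
  ys <- seq(min(b[, 2]), max(b[, 2]), length.out = grid_n)
  grid <- cbind(rep(xs, times = grid_n), rep(ys, each = grid_n))
  inside <- function(e) {
    stats::mahalanobis(grid, e$center, e$covariance) <= e$radius^2
  }
  in1 <- inside(e1); in2 <- inside(e2)
  union <- sum(in1 | in2)
  if (union == 0L) return(0)
  sum(in1 & in2) / union
}

#' Boundary points of a confidence ellipse (for plotting)
#'
#' @param ellipse one element of `confidence_ellipses()$ellipses`.
#' @param n number of boundary points.
#' @return n x 2 matrix tracing the ellipse.
#' @export
ellipse_points <- function(ellipse, n = 181L) {
  theta <- seq(0, 2 * pi, length.out = n)
  circle <- ellipse$radius * cbind(cos(theta), sin(theta))
  sweep(circle %*% chol(ellipse$covariance), 2, ellipse$center, `+`)
}
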