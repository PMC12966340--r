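#' K-means with data-point initialisation
#'
#' Lloyd iterations with centroids initialised by sampling K distinct data
#' vectors, best-of-`restarts` by within-cluster sum of squares (SSE).
#' An empty cluster arising during iteration is reseeded from the point
#' farthest from its centroid. Deterministic given `seed`.
#'
#' @param X numeric matrix, rows = observations (standardized features).
#' @param K number of clusters, `2 <= K <= nrow(X)`.
#' @param seed integer seed (or `NULL` to use the current RNG state).
#' @param restarts independent restarts; the lowest-SSE solution wins.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list of class `pc_clustering`: `K`, `assignments` (1-based),
#'   `centroids` (K x d), `sse`, `sizes`.
#' @export
kmeans_fit <- function(X, K, seed = NULL, restarts = 10, max_iter = 300) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K > n) stop("K exceeds the number of observations", call. = FALSE)
  if (K < 1) stop("K must be positive", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      res <- lloyd_once(X, K, max_iter)
      if (is.null(best) || res$sse < best$sse) best <- res
    }
    best
  })
}

lloyd_once <- function(X, K, max_iter) {
  n <- nrow(X)
  cent <- X[sample.int(n, K), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centroids(X, cent)
    assignment <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      members <- assignment == k
      if (!any(members)) {
        # reseed an empty cluster from the globally farthest point
        far <- which.max(d2[cbind(seq_len(n), assignment)])
        cent[k, ] <- X[far, ]
        assignment[far] <- k
        members <- assignment == k
      }
      cent[k, ] <- colMeans(X[members, , drop = FALSE])
    }
    if (all(assignment == assign_old)) break
    assign_old <- assignment
  }
  d2 <- dist2_to_centroids(X, cent)
  assignment <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(n), assignment)])
  structure(list(K = K, assignments = assignment, centroids = cent,
                 sse = sse, sizes = tabulate(assignment, K)),
            class = "pc_clustering")
}

dist2_to_centroids <- function(X, cent) {
  # squared Euclidean distances, n x K
  xs <- rowSums(X^2)
  cs <- rowSums(cent^2)
  outer(xs, cs, "+") - 2 * X %*% t(cent)
}

#' Cluster-size uniformity score
#'
#' Chi-squared goodness-of-fit of the observed cluster sizes against the
#' uniform expectation `n/K`: `X2 = sum((O_i - n/K)^2 / (n/K))`, returned as
#' the upper-tail p-value at `K - 1` degrees of freedom. Higher means more
#' uniform; a perfectly uniform clustering scores exactly 1.
#'
#' @param sizes integer vector of cluster sizes (or a `pc_clustering`).
#' @return p-value in `[0, 1]`.
#' @export
unif_score <- function(sizes) {
  if (inherits(sizes, "pc_clustering")) sizes <- sizes$sizes
  K <- length(sizes)
  stopifnot(K >= 2)
  n <- sum(sizes)
  expected <- n / K
  x2 <- sum((sizes - expected)^2 / expected)
  stats::pchisq(x2, df = K - 1, lower.tail = FALSE)
}

#' Multi K-means: K sweep selected by size uniformity
#'
#' Runs K-means for every K from `cfg$k_min` to `floor(n/2)`; excludes
#' configurations with an empty cluster or any cluster smaller than
#' `max(2, ceil(0.01 n))` (sparsely populated). Among survivors the
#' selection balances clustering homogeneity against model complexity:
#' K* is the smallest K whose cluster-size distribution the chi-squared
#' uniformity test does not reject at level `cfg$unif_alpha` (a perfectly
#' uniform clustering, p-value 1, at the smallest K therefore always wins);
#' when every K is rejected, the K with the maximal uniformity p-value is
#' taken (ties toward the smallest K). If every K is excluded outright, the
#' sweep falls back to the K with the fewest undersized clusters (logged
#' prominently).
#'
#' @param X standardized feature matrix.
#' @param cfg a [study_config()] (uses `k_min`, `kmeans_restarts`,
#'   `kmeans_max_iter`, `seed`).
#' @param seed overrides `cfg$seed` when given.
#' @return list of class `pc_cluster_result`: `best` (`pc_clustering`),
#'   `K_star`, `selection_scores` (data frame K/score/excluded/reason),
#'   `excluded_Ks`, `method`.
#' @export
multi_kmeans <- function(X, cfg, seed = NULL) {
  sweep_select(X, cfg, seed %||% cfg$seed, criterion = "unif")
}

#' X-means-style sweep: K selected by minimum BIC
#'
#' Same K range and restarts as [multi_kmeans()], selecting the K with the
#' lowest spherical-Gaussian BIC (ties toward the smallest K); no
#' uniformity-based exclusion.
#'
#' @inheritParams multi_kmeans
#' @return a `pc_cluster_result`.
#' @export
xmeans_sweep <- function(X, cfg, seed = NULL) {
  sweep_select(X, cfg, seed %||% cfg$seed, criterion = "bic")
}

sweep_select <- function(X, cfg, seed, criterion = c("unif", "bic")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- nrow(X)
  k_max <- max(cfg$k_min, floor(n / 2))
  if (n < 2 * cfg$k_min) {
    stop("need at least 2*k_min observations for the K sweep", call. = FALSE)
  }
  ks <- seq.int(cfg$k_min, k_max)
  min_size <- max(2, ceiling(0.01 * n))
  fits <- vector("list", length(ks))
  trace <- data.frame(K = ks, score = NA_real_, excluded = FALSE,
                      reason = "", n_undersized = 0L,
                      stringsAsFactors = FALSE)
  for (i in seq_along(ks)) {
    K <- ks[[i]]
    fit <- kmeans_fit(X, K, seed = derive_seed(seed, K),
                      restarts = cfg$kmeans_restarts,
                      max_iter = cfg$kmeans_max_iter)
    fits[[i]] <- fit
    trace$n_undersized[i] <- sum(fit$sizes < min_size)
    if (criterion == "unif") {
      trace$score[i] <- unif_score(fit)
      if (any(fit$sizes == 0)) {
        trace$excluded[i] <- TRUE; trace$reason[i] <- "empty"
      } else if (any(fit$sizes < min_size)) {
        trace$excluded[i] <- TRUE; trace$reason[i] <- "sparse"
      }
    } else {
      trace$score[i] <- bic_score(fit, X)
    }
  }
  ok <- which(!trace$excluded)
  if (length(ok) == 0) {
    pc_log("all K in [%d, %d] excluded; falling back to fewest undersized clusters",
           cfg$k_min, k_max)
    ok <- which(trace$n_undersized == min(trace$n_undersized))
  }
  best_i <- if (criterion == "unif") {
    alpha <- cfg$unif_alpha %||% 0.05
    accepted <- ok[trace$score[ok] >= alpha]
    if (length(accepted) > 0) accepted[1]  # smallest non-rejected K
    else ok[which.max(trace$score[ok])]    # ties -> first, i.e. smallest K
  } else {
    ok[which.min(trace$score[ok])]
  }
  structure(list(best = fits[[best_i]], K_star = ks[[best_i]],
                 selection_scores = trace,
                 excluded_Ks = trace[trace$excluded,
                                     c("K", "reason"), drop = FALSE],
                 method = if (criterion == "unif") "MultiKMeans" else "XMeans"),
            class = "pc_cluster_result")
}

#' Spherical-Gaussian BIC of a clustering
#'
#' Identical-spherical-variance Gaussian mixture likelihood with MLE
#' variance `sigma2 = SSE / (d (n - K))`, mixture weights `n_i / n`,
#' parameter count `p = K d + K + 1` (centroids, weights, shared variance):
#' `BIC = -2 logL + p log(n)`. Lower is better. A zero SSE (exactly
#' duplicated points) floors the variance at a small epsilon.
#'
#' @param clustering a `pc_clustering`.
#' @param X the matrix it was fitted on.
#' @return BIC value (scalar).
#' @export
bic_score <- function(clustering, X) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X); K <- clustering$K
  if (n <= K) stop("BIC needs n > K", call. = FALSE)
  sse <- clustering$sse
  sigma2 <- sse / (d * (n - K))
  if (sigma2 <= 0) sigma2 <- 1e-12
  sizes <- clustering$sizes
  nz <- sizes > 0
  logL <- sum(sizes[nz] * log(sizes[nz] / n)) -
    n * d / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2)
  p <- K * d + K + 1
  -2 * logL + p * log(n)
}

#' @export
print.pc_cluster_result <- function(x, ...) {
  cat(sprintf("%s sweep: K* = %d (%d K values, %d excluded)\n",
              x$method, x$K_star, nrow(x$selection_scores),
              nrow(x$excluded_Ks)))
  invisible(x)
}
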