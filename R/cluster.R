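# Conformational clustering: K-means (k-means++/Lloyd with an inertia
# trace), Gaussian mixture EM (full covariances, log-likelihood trace),
# hierarchical agglomeration (stats::hclust) and spectral clustering, plus
# the silhouette / Calinski-Harabasz quality metrics and summed-rank
# selection of the cluster number.

.new_cluster_result <- function(keys, labels, k, model, x, method) {
  labels <- as.integer(labels)
  stopifnot(all(labels >= 0L & labels < k))
  metrics <- if (k >= 2L && k <= nrow(x) - 1L)
    list(silhouette = silhouette_score(x, labels),
         calinski_harabasz = calinski_harabasz(x, labels))
  else list(silhouette = NA_real_, calinski_harabasz = NA_real_)
  structure(list(keys = keys, labels = labels, k = k, model = model,
                 metrics = metrics, method = method),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", x$method, "with k =", x$k, "\n")
  print(table(label = x$labels))
  cat("silhouette =", signif(x$metrics$silhouette, 4),
      " Calinski-Harabasz =", signif(x$metrics$calinski_harabasz, 4), "\n")
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centroids with
# probability proportional to squared distance from the chosen set.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0)
      probs <- rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

.assign_nearest <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * cross
  list(labels = max.col(-d2, ties.method = "first"),
       d2 = pmax(d2, 0))
}

#' K-means clustering
#'
#' Lloyd iterations from k-means++ seeds; \code{n_init} restarts keep the
#' partition with the lowest inertia (within-cluster sum of squared
#' distances).  Hard (Voronoi) assignment; deterministic for a fixed seed.
#'
#' @param t feature table (or plain numeric matrix).
#' @param k number of clusters, 1 <= k <= rows.
#' @param seed integer RNG seed.
#' @param n_init restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300).
#' @param tol convergence threshold on the Frobenius norm of the centroid
#'   update, relative to the data spread (default 1e-4).
#' @return a \code{cluster_result}; \code{model} carries \code{centers},
#'   \code{inertia} and the per-iteration \code{inertia_trace} of the
#'   winning restart.
#' @export
kmeans_cluster <- function(t, k, seed = 0L, n_init = 10L, max_iter = 300L,
                           tol = 1e-4) {
  fm <- .as_fm(t)
  x <- fm$x
  n <- nrow(x)
  if (k < 1L || k > n) stop("k must be between 1 and the row count (", n, ")")
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_init)) {
    centers <- .kmeanspp_init(x, k)
    trace <- numeric(0)
    labels <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      asg <- .assign_nearest(x, centers)
      labels <- asg$labels
      inertia <- sum(asg$d2[cbind(seq_len(n), labels)])
      trace <- c(trace, inertia)
      new_centers <- centers
      for (j in seq_len(k)) {
        members <- labels == j
        if (!any(members)) {
          # empty cluster: grab the point farthest from its centroid
          far <- which.max(asg$d2[cbind(seq_len(n), labels)])
          new_centers[j, ] <- x[far, ]
        } else new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
      shift <- sqrt(sum((new_centers - centers)^2))
      centers <- new_centers
      if (shift < tol * sqrt(sum(apply(x, 2, stats::var)) + 1e-300)) break
    }
    asg <- .assign_nearest(x, centers)
    inertia <- sum(asg$d2[cbind(seq_len(n), asg$labels)])
    if (is.null(best) || inertia < best$inertia)
      best <- list(centers = centers, labels = asg$labels, inertia = inertia,
                   trace = trace)
  }
  .new_cluster_result(fm$keys, best$labels - 1L, k,
                      list(centers = best$centers, inertia = best$inertia,
                           inertia_trace = best$trace),
                      x, "kmeans")
}

# log N(x | mu, Sigma) for all rows, via Cholesky.
.log_dmvnorm <- function(x, mu, Sigma) {
  p <- ncol(x)
  ch <- chol(Sigma)
  centered <- sweep(x, 2, mu)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Gaussian mixture model clustering (EM)
#'
#' Full-covariance EM initialised from a k-means partition; covariances are
#' regularised by adding \code{reg_covar} to the diagonal.  Labels are the
#' argmax responsibilities (soft assignments are retained in the model).
#'
#' @inheritParams kmeans_cluster
#' @param max_iter EM iteration cap (default 200).
#' @param tol convergence threshold on the change in mean log-likelihood
#'   (default 1e-3).
#' @param reg_covar diagonal covariance regularisation (default 1e-6).
#' @return a \code{cluster_result}; \code{model} carries \code{weights},
#'   \code{means}, \code{covariances}, \code{responsibilities} and the
#'   per-iteration \code{loglik_trace}.
#' @export
gmm_cluster <- function(t, k, seed = 0L, max_iter = 200L, tol = 1e-3,
                        reg_covar = 1e-6) {
  fm <- .as_fm(t)
  x <- fm$x
  n <- nrow(x); p <- ncol(x)
  if (n <= k) stop("need more rows than clusters")
  km <- kmeans_cluster(t, k, seed = seed, n_init = 5L)
  labels <- km$labels + 1L
  weights <- tabulate(labels, k) / n
  means <- km$model$centers
  covs <- array(0, c(k, p, p))
  for (j in seq_len(k)) {
    xj <- x[labels == j, , drop = FALSE]
    cv <- if (nrow(xj) > 1L) stats::cov(xj) * (nrow(xj) - 1) / nrow(xj)
          else diag(p) * 0
    covs[j, , ] <- cv + diag(reg_covar, p)
  }
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  resp <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    # E step
    logdens <- vapply(seq_len(k), function(j)
      log(weights[j]) + .log_dmvnorm(x, means[j, ], covs[j, , ]),
      numeric(n))
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    resp <- exp(logdens - lse)
    ll <- mean(lse)
    loglik_trace <- c(loglik_trace, ll)
    if (abs(ll - prev_ll) < tol) break
    prev_ll <- ll
    # M step
    nk <- colSums(resp) + 1e-300
    weights <- nk / n
    means <- t(resp) %*% x / nk
    for (j in seq_len(k)) {
      centered <- sweep(x, 2, means[j, ])
      cv <- t(centered * resp[, j]) %*% centered / nk[j]
      covs[j, , ] <- cv + diag(reg_covar, p)
    }
  }
  if (any(!is.finite(loglik_trace)))
    stop("GMM log-likelihood diverged (singular covariance?)")
  labels <- max.col(resp, ties.method = "first") - 1L
  # guard against empty argmax clusters (relabel to 0..k'-1 is NOT done:
  # k is the model order; empty components keep their slot in the model)
  .new_cluster_result(fm$keys, labels, k,
                      list(weights = weights, means = means,
                           covariances = covs, responsibilities = resp,
                           loglik_trace = loglik_trace),
                      x, "gmm")
}

#' Sample from a fitted Gaussian mixture
#'
#' Draws \code{n} points from the mixture stored in a GMM
#' \code{cluster_result}, e.g. to generate geometries-like feature vectors
#' from a selected region of conformational space.
#'
#' @param result a \code{cluster_result} from \code{\link{gmm_cluster}}.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @return list with \code{x} (samples) and \code{component} (1-based).
#' @export
gmm_sample <- function(result, n, seed = 0L) {
  stopifnot(result$method == "gmm")
  set.seed(seed)
  m <- result$model
  k <- length(m$weights)
  comp <- sample.int(k, n, replace = TRUE, prob = m$weights)
  p <- ncol(m$means)
  x <- matrix(0, n, p)
  for (j in seq_len(k)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    ch <- chol(m$covariances[j, , ])
    x[idx, ] <- matrix(stats::rnorm(length(idx) * p), length(idx), p) %*% ch +
      matrix(m$means[j, ], length(idx), p, byrow = TRUE)
  }
  list(x = x, component = comp)
}

#' Hierarchical agglomerative clustering
#'
#' Bottom-up merging via \code{stats::hclust} on Euclidean distances, cut at
#' \code{k} clusters.  Default linkage is Ward's minimum-variance criterion
#' (\code{ward.D2}); \code{average}, \code{complete} and \code{single} are
#' also supported.  Fully deterministic.
#'
#' @inheritParams kmeans_cluster
#' @param linkage one of \code{"ward"}, \code{"average"}, \code{"complete"},
#'   \code{"single"}.
#' @return a \code{cluster_result}; \code{model} carries the \code{hclust}
#'   merge tree.
#' @export
hierarchical_cluster <- function(t, k,
                                 linkage = c("ward", "average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  fm <- .as_fm(t)
  if (k < 1L || k > nrow(fm$x)) stop("k must be between 1 and the row count")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(fm$x), method = method)
  labels <- stats::cutree(hc, k = k)
  # relabel by first appearance for stability
  labels <- match(labels, unique(labels)) - 1L
  .new_cluster_result(fm$keys, labels, k, list(tree = hc, linkage = linkage),
                      fm$x, "hierarchical")
}

#' Spectral clustering
#'
#' RBF affinity A_ij = exp(-gamma |x_i - x_j|^2) with gamma = 1/n_features,
#' symmetric normalised Laplacian, bottom-k eigenvectors (row-normalised)
#' and k-means on the resulting spectral embedding.
#'
#' @inheritParams kmeans_cluster
#' @param gamma RBF width parameter; default \code{1/n_features}.
#' @return a \code{cluster_result}; \code{model} carries the Laplacian
#'   eigenvalues and the spectral embedding.
#' @export
spectral_cluster <- function(t, k, seed = 0L, gamma = NULL) {
  fm <- .as_fm(t)
  x <- fm$x
  n <- nrow(x)
  if (n <= k) stop("need more rows than clusters")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  A <- exp(-gamma * as.matrix(stats::dist(x))^2)
  diag(A) <- 0
  deg <- rowSums(A)
  if (any(deg <= 0))
    stop("degenerate affinity: ", sum(deg <= 0), " all-zero affinity rows")
  Dm <- 1 / sqrt(deg)
  M <- A * (Dm %o% Dm)          # D^-1/2 A D^-1/2 = I - L_sym
  e <- eigen(M, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  km <- kmeans_cluster(cbind(fm$keys, as.data.frame(U)), k, seed = seed)
  .new_cluster_result(fm$keys, km$labels, k,
                      list(laplacian_eigenvalues = 1 - e$values,
                           embedding = U),
                      x, "spectral")
}

.as_fm <- function(t) {
  if (is.matrix(t)) {
    list(keys = data.frame(traj = rep(NA_integer_, nrow(t)),
                           time = seq_len(nrow(t)) - 1),
         x = t)
  } else feature_matrix(t)
}

#' Mean silhouette score of a partition
#'
#' For each point, a = mean distance to its own cluster, b = smallest mean
#' distance to another cluster; the score is the mean of (b - a)/max(a, b).
#'
#' @param t feature table or numeric matrix.
#' @param labels integer cluster labels (0-based), 2 <= k <= rows - 1.
#' @return numeric in [-1, 1].
#' @export
silhouette_score <- function(t, labels) {
  x <- .as_fm(t)$x
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette undefined for a single cluster")
  if (length(ks) > nrow(x) - 1L) stop("silhouette needs k <= rows - 1")
  D <- as.matrix(stats::dist(x))
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(ks[ks != labels[i]], function(kk)
      mean(D[i, labels == kk]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index of a partition
#'
#' Ratio of between- to within-cluster dispersion scaled by
#' (n - k)/(k - 1); zero within-cluster dispersion is guarded with
#' epsilon = 1e-12 so perfectly tight clusters give a large finite value.
#'
#' @inheritParams silhouette_score
#' @return non-negative numeric.
#' @export
calinski_harabasz <- function(t, labels) {
  x <- .as_fm(t)$x
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  k <- length(ks)
  n <- nrow(x)
  if (k < 2L) stop("Calinski-Harabasz undefined for a single cluster")
  grand <- colMeans(x)
  wss <- 0; bss <- 0
  for (kk in ks) {
    xj <- x[labels == kk, , drop = FALSE]
    cj <- colMeans(xj)
    wss <- wss + sum(sweep(xj, 2, cj)^2)
    bss <- bss + nrow(xj) * sum((cj - grand)^2)
  }
  (bss / max(wss, 1e-12)) * (n - k) / (k - 1)
}

#' Select the cluster number by combined quality metrics
#'
#' For each candidate k the chosen algorithm is run and both the silhouette
#' and the Calinski-Harabasz scores are computed.  The candidates are ranked
#' separately by each metric (higher is better) and the k with the smallest
#' summed rank wins; ties go to the smallest k.
#'
#' @param t feature table or matrix.
#' @param k_range integer candidates, subset of [2, rows - 1].
#' @param algorithm one of \code{"kmeans"}, \code{"gmm"},
#'   \code{"hierarchical"}, \code{"spectral"}.
#' @param seed integer RNG seed (passed to the algorithm).
#' @return the selected k (integer); attribute \code{"scores"} holds the
#'   per-k metric table.
#' @export
select_k_best <- function(t, k_range = 2:6,
                          algorithm = c("kmeans", "gmm", "hierarchical",
                                        "spectral"),
                          seed = 0L) {
  algorithm <- match.arg(algorithm)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k_range")
  n <- nrow(.as_fm(t)$x)
  if (any(k_range < 2L | k_range > n - 1L))
    stop("k_range must lie within [2, rows - 1]")
  sil <- ch <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    res <- run_clustering(t, algorithm, k_range[i], seed = seed)
    sil[i] <- res$metrics$silhouette
    ch[i] <- res$metrics$calinski_harabasz
  }
  # rank 1 = best (highest); average ranks for ties keeps the rule scale-free
  rank_sum <- rank(-sil, ties.method = "average") +
    rank(-ch, ties.method = "average")
  best <- k_range[which.min(rank_sum)]  # which.min takes the first = smallest k
  attr(best, "scores") <- data.frame(k = k_range, silhouette = sil,
                                     calinski_harabasz = ch,
                                     rank_sum = rank_sum)
  best
}

#' Run a clustering algorithm by name
#' @param t feature table or matrix.
#' @param algorithm algorithm name.
#' @param k cluster count.
#' @param seed integer RNG seed.
#' @param ... passed to the algorithm.
#' @return a \code{cluster_result}.
#' @export
run_clustering <- function(t, algorithm, k, seed = 0L, ...) {
  switch(algorithm,
         kmeans = kmeans_cluster(t, k, seed = seed, ...),
         gmm = gmm_cluster(t, k, seed = seed, ...),
         hierarchical = hierarchical_cluster(t, k, ...),
         spectral = spectral_cluster(t, k, seed = seed, ...),
         stop("unknown algorithm: ", algorithm))
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement in [-1, 1]; 1 means identical partitions
#' up to relabelling.  Used to validate recovered clusters against planted
#' ground-truth labels.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
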