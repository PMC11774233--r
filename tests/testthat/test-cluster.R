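# K-means, GMM, hierarchical, spectral clustering, quality metrics and
# cluster-number selection.

two_blobs <- function(n = 50, gap = 100, sd = 1, seed = 50) {
  set.seed(seed)
  list(t = as_ftable(rbind(matrix(stats::rnorm(2 * n, sd = sd), n, 2),
                           matrix(stats::rnorm(2 * n, sd = sd) + gap, n, 2))),
       labels = rep(0:1, each = n))
}

test_that("k-means: k=1 centroid, planted blobs, monotone inertia", {
  b <- two_blobs()
  k1 <- kmeans_cluster(b$t, 1, seed = 1)
  expect_true(all(k1$labels == 0))
  expect_equal(as.numeric(k1$model$centers),
               unname(colMeans(feature_matrix(b$t)$x)), tolerance = 1e-10)

  k2 <- kmeans_cluster(b$t, 2, seed = 1)
  expect_equal(adjusted_rand_index(k2$labels, b$labels), 1)
  expect_true(all(diff(k2$model$inertia_trace) <= 1e-9))
  # Voronoi property: every point nearest its own centroid
  x <- feature_matrix(b$t)$x
  nearest <- apply(x, 1, function(p)
    which.min(colSums((t(k2$model$centers) - p)^2))) - 1L
  expect_identical(as.integer(nearest), k2$labels)
  # deterministic per seed
  expect_identical(kmeans_cluster(b$t, 2, seed = 9)$labels,
                   kmeans_cluster(b$t, 2, seed = 9)$labels)
  expect_error(kmeans_cluster(b$t, 1000, seed = 1), "between 1 and")
})

test_that("GMM: responsibilities, monotone log-likelihood, mean recovery", {
  set.seed(51)
  X <- rbind(matrix(stats::rnorm(2000), 1000, 2) + 5,
             matrix(stats::rnorm(2000), 1000, 2) - 5)
  res <- gmm_cluster(as_ftable(X), 2, seed = 3)
  expect_equal(rowSums(res$model$responsibilities), rep(1, 2000),
               tolerance = 1e-9)
  expect_true(all(diff(res$model$loglik_trace) >= -1e-9))
  means <- res$model$means[order(res$model$means[, 1]), ]
  expect_equal(as.numeric(means), c(-5, 5, -5, 5), tolerance = 0.1)
  expect_equal(adjusted_rand_index(res$labels, rep(0:1, each = 1000)), 1)
})

test_that("GMM is generative: sampling and refitting recovers the means", {
  set.seed(52)
  X <- rbind(matrix(stats::rnorm(600, sd = 0.5), 300, 2) + 4,
             matrix(stats::rnorm(600, sd = 0.5), 300, 2) - 4)
  fit <- gmm_cluster(as_ftable(X), 2, seed = 1)
  draws <- gmm_sample(fit, 600, seed = 2)
  refit <- gmm_cluster(as_ftable(draws$x), 2, seed = 3)
  m1 <- fit$model$means[order(fit$model$means[, 1]), ]
  m2 <- refit$model$means[order(refit$model$means[, 1]), ]
  # within 3 standard errors: se ~ sd/sqrt(n_k) = 0.5/sqrt(300)
  expect_lt(max(abs(m1 - m2)), 3 * 0.5 / sqrt(300) * sqrt(2))
})

test_that("hierarchical clustering cuts the dendrogram as requested", {
  b <- two_blobs(n = 10)
  expect_equal(hierarchical_cluster(b$t, 1)$k, 1)
  expect_true(all(hierarchical_cluster(b$t, 1)$labels == 0))
  singl <- hierarchical_cluster(b$t, 20)
  expect_equal(sort(unique(singl$labels)), 0:19)
  h2 <- hierarchical_cluster(b$t, 2)
  expect_equal(adjusted_rand_index(h2$labels, b$labels), 1)
  # merge heights non-decreasing (guaranteed for ward/complete/average)
  for (lk in c("ward", "average", "complete", "single")) {
    hres <- hierarchical_cluster(b$t, 2, linkage = lk)
    expect_true(all(diff(hres$model$tree$height) >= -1e-9))
  }
})

test_that("hierarchical merges agree with a brute-force single-linkage oracle", {
  set.seed(53)
  x <- matrix(stats::rnorm(24), 12, 2)
  hres <- hierarchical_cluster(as_ftable(x), 3, linkage = "single")
  # oracle: iterative minimum-distance merging
  groups <- as.list(seq_len(12))
  D <- as.matrix(stats::dist(x))
  heights <- numeric(0)
  while (length(groups) > 3) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      d <- min(D[groups[[i]], groups[[j]]])
      if (d < best[1]) best <- c(d, j, i)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  oracle_labels <- integer(12)
  for (gi in seq_along(groups)) oracle_labels[groups[[gi]]] <- gi
  expect_equal(adjusted_rand_index(hres$labels, oracle_labels), 1)
  expect_equal(utils::head(hres$model$tree$height, length(heights)),
               heights, tolerance = 1e-10)
})

test_that("spectral clustering separates concentric rings", {
  set.seed(54)
  th <- stats::runif(200, 0, 2 * pi)
  X <- rbind(cbind(cos(th), sin(th)), cbind(5 * cos(th), 5 * sin(th))) +
    matrix(stats::rnorm(800, sd = 0.05), 400, 2)
  truth <- rep(0:1, each = 200)
  sres <- spectral_cluster(as_ftable(X), 2, seed = 1)
  expect_equal(adjusted_rand_index(sres$labels, truth), 1)
  # k-means alone fails this geometry
  kres <- kmeans_cluster(as_ftable(X), 2, seed = 1)
  expect_lt(adjusted_rand_index(kres$labels, truth), 0.5)
  # normalised Laplacian is PSD
  expect_gt(min(sres$model$laplacian_eigenvalues), -1e-10)
  # duplicate points share a label
  dup <- as_ftable(rbind(X[1, ], X[1, ], X[250, ], X[250, ]))
  dres <- spectral_cluster(dup, 2, seed = 1)
  expect_equal(dres$labels[1], dres$labels[2])
  expect_equal(dres$labels[3], dres$labels[4])
})

test_that("silhouette matches its formula and flags degenerate input", {
  b <- two_blobs(n = 3, gap = 50)
  s <- silhouette_score(b$t, b$labels)
  expect_gt(s, 0.95)
  # direct formula oracle on the 6 points
  x <- feature_matrix(b$t)$x
  D <- as.matrix(stats::dist(x))
  sil <- vapply(1:6, function(i) {
    own <- b$labels == b$labels[i]
    a <- sum(D[i, own]) / (sum(own) - 1)
    bo <- mean(D[i, !own])
    (bo - a) / max(a, bo)
  }, numeric(1))
  expect_equal(s, mean(sil), tolerance = 1e-12)
  # random labels on one blob: near zero
  set.seed(55)
  one <- as_ftable(matrix(stats::rnorm(400), 200, 2))
  expect_lt(abs(silhouette_score(one, sample(0:1, 200, TRUE))), 0.05)
  expect_error(silhouette_score(one, rep(0, 200)), "single cluster")
})

test_that("silhouette agrees with the cluster package implementation", {
  set.seed(56)
  x <- matrix(stats::rnorm(180), 60, 3)
  lab <- sample(0:2, 60, TRUE)
  mine <- silhouette_score(as_ftable(x), lab)
  ref <- mean(cluster::silhouette(lab + 1, stats::dist(x))[, "sil_width"])
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("Calinski-Harabasz matches pencil-and-paper arithmetic", {
  # 1-D: {0, 1} vs {10, 11}; grand mean 5.5, cluster means 0.5 / 10.5
  # bss = 2*(5^2)*2 = 100, wss = 4*0.25 = 1, CH = (100/1)*(4-2)/(2-2+1)
  t1 <- as_ftable(matrix(c(0, 1, 10, 11), 4, 1))
  lab <- c(0, 0, 1, 1)
  expect_equal(calinski_harabasz(t1, lab), (100 / 1) * (4 - 2) / (2 - 1))
  # degenerate zero-within case stays finite and large
  t2 <- as_ftable(matrix(c(0, 0, 10, 10), 4, 1))
  ch <- calinski_harabasz(t2, lab)
  expect_true(is.finite(ch) && ch > 1e10)
  # translation invariance
  t3 <- t1; t3$V1 <- t3$V1 + 123.4
  expect_equal(calinski_harabasz(t3, lab), calinski_harabasz(t1, lab),
               tolerance = 1e-9)
})

test_that("select_k_best recovers three planted blobs and breaks ties low", {
  set.seed(57)
  X <- rbind(matrix(stats::rnorm(200, sd = 0.5), 100, 2),
             matrix(stats::rnorm(200, sd = 0.5) + 20, 100, 2),
             cbind(stats::rnorm(100, sd = 0.5) + 20,
                   stats::rnorm(100, sd = 0.5) - 20))
  t1 <- as_ftable(X)
  expect_equal(as.integer(select_k_best(t1, 2:6, "kmeans", seed = 1)), 3L)
  expect_equal(as.integer(select_k_best(t1, 2, "kmeans", seed = 1)), 2L)
  expect_error(select_k_best(t1, integer(0), "kmeans"), "empty k_range")
  expect_error(select_k_best(t1, 1:3, "kmeans"), "k_range")
})

test_that("adjusted Rand index matches the mclust reference", {
  set.seed(58)
  for (i in 1:10) {
    a <- sample(1:4, 80, TRUE)
    b <- sample(1:3, 80, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})
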