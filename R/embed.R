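# Dimensionality reduction: PCA, ISOMAP (kNN graph + Dijkstra geodesics +
# classical MDS) and an exact t-SNE.  Each returns an `embedding`: keys +
# coordinate matrix + method diagnostics.

.new_embedding <- function(keys, coords, method, meta) {
  colnames(coords) <- paste0("X", seq_len(ncol(coords)))
  structure(list(keys = keys, coords = coords, method = method, meta = meta),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding:", x$method, "-", nrow(x$coords), "points in",
      ncol(x$coords), "dimensions\n")
  invisible(x)
}

#' Convert an embedding to a data.frame
#' @param x an \code{embedding}.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return data.frame traj, time, X1..Xd.
#' @export
as.data.frame.embedding <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  cbind(x$keys, as.data.frame(x$coords))
}

# Sign convention shared by PCA and the MDS step of ISOMAP: orient each
# axis so its largest-magnitude loading (or coordinate) is positive.
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Principal component analysis
#'
#' Column-centred data projected on the top right-singular vectors
#' (via \code{stats::prcomp}); components are ordered by decreasing
#' explained variance, and each axis is oriented so that its
#' largest-magnitude loading is positive (bit-stable across runs).
#'
#' @param t feature table.
#' @param n_components number of components, <= min(rows - 1, features).
#' @return an \code{embedding}; \code{meta$explained_variance_ratio} holds
#'   the per-component variance fractions (of the total data variance) and
#'   \code{meta$loadings} the oriented loading matrix.
#' @export
pca_fit_transform <- function(t, n_components = 2L) {
  fm <- feature_matrix(t)
  n <- nrow(fm$x); p <- ncol(fm$x)
  if (n_components > min(n - 1L, p))
    stop("n_components (", n_components, ") exceeds min(rows-1, features) = ",
         min(n - 1L, p))
  pc <- stats::prcomp(fm$x, center = TRUE, scale. = FALSE)
  W <- .fix_signs(pc$rotation[, seq_len(n_components), drop = FALSE])
  scores <- sweep(fm$x, 2, pc$center) %*% W
  total_var <- sum(pc$sdev^2)
  evr <- (pc$sdev^2 / total_var)[seq_len(n_components)]
  .new_embedding(fm$keys, scores, "pca",
                 list(explained_variance_ratio = evr, loadings = W,
                      center = pc$center))
}

#' ISOMAP embedding
#'
#' Builds a k-nearest-neighbour graph (symmetrised by union, Euclidean edge
#' weights), computes all-pairs shortest-path geodesic distances with
#' Dijkstra's algorithm, and applies classical MDS to the double-centred
#' squared geodesics.  Negative MDS eigenvalues are clamped at zero and
#' their total magnitude reported as the reconstruction residual.
#'
#' @param t feature table.
#' @param n_neighbors neighbourhood size for the graph (default 30).
#' @param n_components embedding dimension (default 2).
#' @return an \code{embedding}; \code{meta$residual} is the clamped negative
#'   eigenvalue mass.
#' @export
isomap_fit_transform <- function(t, n_neighbors = 30L, n_components = 2L) {
  fm <- feature_matrix(t)
  n <- nrow(fm$x)
  if (n_neighbors < 1L) stop("n_neighbors must be >= 1")
  if (n_neighbors >= n) n_neighbors <- n - 1L
  D <- as.matrix(stats::dist(fm$x))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(n_neighbors + 1L)]
    edges <- rbind(edges, cbind(i, nb))
  }
  und <- unique(t(apply(edges, 1, sort)))  # union symmetrisation
  gr <- igraph::graph_from_edgelist(und, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  igraph::E(gr)$weight <- D[und]
  comp <- igraph::components(gr)
  if (comp$no > 1L)
    stop("neighbourhood graph is disconnected (component sizes: ",
         paste(comp$csize, collapse = ", "),
         "); increase n_neighbors")
  geo <- igraph::distances(gr, algorithm = "dijkstra")
  mds <- stats::cmdscale(geo, k = n_components, eig = TRUE)
  if (ncol(mds$points) < n_components)
    stop("geodesic MDS yielded fewer than ", n_components, " dimensions")
  neg <- sum(abs(mds$eig[mds$eig < 0]))
  if (neg > 0)
    message("isomap: clamped negative MDS eigenvalue mass ", signif(neg, 4))
  coords <- .fix_signs(mds$points[, seq_len(n_components), drop = FALSE])
  .new_embedding(fm$keys, coords, "isomap",
                 list(residual = neg, n_neighbors = n_neighbors))
}

#' t-SNE embedding
#'
#' Exact (dense) t-distributed stochastic neighbour embedding: Gaussian
#' input affinities calibrated per point to the requested perplexity by
#' bisection, Student-t output kernel, gradient descent with momentum and
#' early exaggeration.  Deterministic for a fixed seed.
#'
#' @param t feature table.
#' @param perplexity effective neighbour count; must be < rows / 3.
#' @param n_components embedding dimension (default 2).
#' @param seed integer RNG seed (initialisation is random).
#' @param max_iter gradient-descent iterations.
#' @param learning_rate step size.
#' @return an \code{embedding}; \code{meta$kl_divergence} holds the final
#'   objective value.
#' @export
tsne_fit_transform <- function(t, perplexity = 30, n_components = 2L,
                               seed = 0L, max_iter = 500L,
                               learning_rate = 200) {
  fm <- feature_matrix(t)
  n <- nrow(fm$x)
  if (perplexity >= n / 3)
    stop("perplexity (", perplexity, ") must be < rows/3 = ", n / 3)
  P <- .tsne_affinities(fm$x, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * n_components, sd = 1e-4), n, n_components)
  G <- matrix(0, n, n_components)
  gains <- matrix(1, n, n_components)
  exag_until <- 100L
  Pe <- P * 12  # early exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == exag_until + 1L) Pe <- P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Qd <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Qd) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- mom * G - learning_rate * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
  diag(num) <- 0
  Qd <- pmax(num / sum(num), 1e-12)
  kl <- sum(P * log(P / Qd))
  .new_embedding(fm$keys, Y, "tsne",
                 list(kl_divergence = kl, perplexity = perplexity,
                      seed = seed))
}

# Conditional Gaussian affinities with per-point bandwidth calibrated to
# log(perplexity) by bisection on the precision beta.
.tsne_affinities <- function(x, perplexity, tol = 1e-5) {
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { H <- 0; p[] <- 0 }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}
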