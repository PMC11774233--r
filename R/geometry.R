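#' Molecular geometry object
#'
#' A \code{geometry} is the basic structural unit of the package: a set of
#' atoms with element labels and Cartesian coordinates in Angstrom.
#'
#' @param labels character vector of element symbols, one per atom.
#' @param coords numeric matrix of shape (n_atoms, 3), Cartesian positions
#'   in Angstrom.
#' @return An object of class \code{geometry} with components \code{labels}
#'   and \code{coords}.
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(g)
#' @export
geometry <- function(labels, coords) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("coords must be an (n_atoms x 3) matrix")
  labels <- as.character(labels)
  if (length(labels) < 1L)
    stop("geometry needs at least one atom")
  if (length(labels) != nrow(coords))
    stop("labels length (", length(labels),
         ") does not match coordinate rows (", nrow(coords), ")")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(labels = labels, coords = coords), class = "geometry")
}

#' Number of atoms in a geometry
#' @param g a \code{geometry}.
#' @return integer atom count.
#' @export
n_atoms <- function(g) {
  stopifnot(inherits(g, "geometry"))
  length(g$labels)
}

#' @export
print.geometry <- function(x, ...) {
  cat("geometry:", n_atoms(x), "atoms (",
      paste(unique(x$labels), collapse = " "), ")\n")
  invisible(x)
}

#' Apply a rigid-body motion to a geometry
#'
#' Rotates by matrix \code{R} then translates by vector \code{t}.  Used
#' mainly in invariance tests: all descriptors in the package are unchanged
#' under such motions.
#'
#' @param g a \code{geometry}.
#' @param R 3x3 rotation matrix (orthogonal, det +1).
#' @param t length-3 translation vector, Angstrom.
#' @return transformed \code{geometry}.
#' @export
transform_geometry <- function(g, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(inherits(g, "geometry"))
  geometry(g$labels, g$coords %*% t(R) + matrix(t, n_atoms(g), 3, byrow = TRUE))
}

#' Draw a uniformly random rotation matrix
#'
#' Uses the QR decomposition of a Gaussian matrix with sign correction so the
#' result is Haar-distributed over SO(3).
#'
#' @param seed optional integer seed.
#' @return 3x3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
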