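# Invariant geometric descriptors: pairwise-distance (R2) family and
# Z-matrix internal coordinates.  All outputs are invariant to global
# rotation and translation of the input geometry.

#' Pairwise-distance (R2) descriptor
#'
#' Flattens the strict lower triangle of the interatomic Euclidean distance
#' matrix, row-major, giving n(n-1)/2 features named \code{R_i_j} with
#' i > j (0-based atom indices).
#'
#' @param g a \code{geometry} with at least two atoms.
#' @return named numeric vector of length n(n-1)/2, Angstrom.
#' @examples
#' g <- geometry(c("C", "C", "C"), rbind(c(0,0,0), c(1,0,0), c(0,1,0)))
#' pairwise_distance_vector(g)  # 1, 1, sqrt(2)
#' @export
pairwise_distance_vector <- function(g) {
  stopifnot(inherits(g, "geometry"))
  n <- n_atoms(g)
  if (n < 2L) stop("pairwise distances need at least 2 atoms")
  d <- as.matrix(stats::dist(g$coords))
  idx <- which(lower.tri(d), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # row-major
  v <- d[idx]
  names(v) <- sprintf("R_%d_%d", idx[, 1] - 1L, idx[, 2] - 1L)
  v
}

#' R2 descriptor variants
#'
#' Transforms a pairwise-distance vector into one of the derived
#' descriptors: \code{inverse} (1/R, Coulomb-matrix-like), \code{delta}
#' (R(t) - R(ref)) or \code{re} (R(ref)/R(t), relative-to-equilibrium).
#'
#' @param v pairwise-distance vector of the current geometry.
#' @param v_ref pairwise-distance vector of the reference geometry
#'   (required for \code{delta} and \code{re}).
#' @param variant one of \code{"inverse"}, \code{"delta"}, \code{"re"}.
#' @return numeric vector, same length and names as \code{v}.
#' @export
r2_variant <- function(v, v_ref = NULL, variant = c("inverse", "delta", "re")) {
  variant <- match.arg(variant)
  if (variant %in% c("delta", "re")) {
    if (is.null(v_ref)) stop("variant '", variant, "' needs v_ref")
    if (length(v) != length(v_ref))
      stop("v and v_ref lengths differ (", length(v), " vs ",
           length(v_ref), ")")
  }
  switch(variant,
    inverse = {
      if (any(v <= 0)) stop("zero or negative distance: inverse undefined")
      1 / v
    },
    delta = v - v_ref,
    re = {
      if (any(v <= 0)) stop("zero or negative distance: re undefined")
      v_ref / v
    })
}

#' Distance between two atoms
#' @param g a \code{geometry}.
#' @param i,j 1-based atom indices.
#' @return distance in Angstrom.
#' @export
bond_length <- function(g, i, j) {
  sqrt(sum((g$coords[i, ] - g$coords[j, ])^2))
}

#' Bond angle at a vertex atom
#'
#' Angle i-j-k with vertex at j, from the arccosine of the normalised dot
#' product of the two bond vectors.
#'
#' @param g a \code{geometry}.
#' @param i,j,k distinct 1-based atom indices; vertex at \code{j}.
#' @return angle in degrees, in [0, 180].
#' @export
bond_angle <- function(g, i, j, k) {
  if (length(unique(c(i, j, k))) != 3L) stop("atoms must be distinct")
  u <- g$coords[i, ] - g$coords[j, ]
  w <- g$coords[k, ] - g$coords[j, ]
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-12 || nw < 1e-12) stop("coincident atoms: angle undefined")
  cosang <- sum(u * w) / (nu * nw)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Signed dihedral (torsion) angle
#'
#' IUPAC right-handed convention: with b1 = r_j - r_i, b2 = r_k - r_j,
#' b3 = r_l - r_k, n1 = b1 x b2, n2 = b2 x b3, the torsion is
#' atan2((n1 x n2) . b2/|b2|, n1 . n2), mapped to (-180, 180].
#'
#' @param g a \code{geometry}.
#' @param i,j,k,l four distinct 1-based atom indices along the chain.
#' @return signed torsion in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(g, i, j, k, l) {
  if (length(unique(c(i, j, k, l))) != 4L) stop("atoms must be distinct")
  b1 <- g$coords[j, ] - g$coords[i, ]
  b2 <- g$coords[k, ] - g$coords[j, ]
  b3 <- g$coords[l, ] - g$coords[k, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("collinear backbone: dihedral undefined")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default sequential Z-matrix connectivity
#'
#' Atom i (1-based, i >= 2) bonds to i-1, makes an angle with i-2 and a
#' dihedral with i-3, following input atom order.
#'
#' @param n atom count.
#' @return data.frame with columns \code{atom}, \code{bond}, \code{angle},
#'   \code{dihedral} (NA where undefined).
#' @export
default_connectivity <- function(n) {
  if (n < 2L) stop("Z-matrix needs at least 2 atoms")
  data.frame(atom = seq_len(n),
             bond = c(NA, seq_len(n - 1L)),
             angle = c(NA, NA, seq_len(max(n - 2L, 0L)))[seq_len(n)],
             dihedral = c(NA, NA, NA, seq_len(max(n - 3L, 0L)))[seq_len(n)])
}

.check_connectivity <- function(conn, n) {
  need <- c("atom", "bond", "angle", "dihedral")
  if (!all(need %in% names(conn))) stop("connectivity needs columns ",
                                        paste(need, collapse = ", "))
  if (nrow(conn) != n) stop("connectivity rows (", nrow(conn),
                            ") != atom count (", n, ")")
  for (r in seq_len(nrow(conn))) {
    refs <- stats::na.omit(unlist(conn[r, c("bond", "angle", "dihedral")]))
    if (any(refs >= conn$atom[r]))
      stop("connectivity row ", r,
           ": reference to an atom not yet defined (later index)")
  }
  invisible(conn)
}

#' Z-matrix internal coordinates
#'
#' Converts Cartesian coordinates to internal coordinates: n-1 bond lengths
#' (Angstrom), n-2 bond angles (degrees, [0, 180]) and n-3 dihedrals
#' (degrees, (-180, 180]), 3n-6 features in total for n >= 4.
#'
#' @param g a \code{geometry} with n >= 2 atoms.
#' @param connectivity optional connectivity table as returned by
#'   \code{\link{default_connectivity}}; each atom may only reference
#'   earlier-indexed atoms.
#' @return object of class \code{zmatrix}: list with \code{connectivity},
#'   \code{bonds}, \code{angles}, \code{dihedrals} (named vectors).
#' @export
zmatrix <- function(g, connectivity = NULL) {
  stopifnot(inherits(g, "geometry"))
  n <- n_atoms(g)
  if (is.null(connectivity)) connectivity <- default_connectivity(n)
  .check_connectivity(connectivity, n)
  bonds <- numeric(0); angles <- numeric(0); dihedrals <- numeric(0)
  for (r in seq_len(n)) {
    a <- connectivity$atom[r]
    b <- connectivity$bond[r]
    an <- connectivity$angle[r]
    d <- connectivity$dihedral[r]
    if (!is.na(b)) {
      bonds[sprintf("B_%d_%d", a - 1L, b - 1L)] <- bond_length(g, a, b)
    }
    if (!is.na(an)) {
      angles[sprintf("A_%d_%d_%d", a - 1L, b - 1L, an - 1L)] <-
        bond_angle(g, a, b, an)
    }
    if (!is.na(d)) {
      dihedrals[sprintf("D_%d_%d_%d_%d", a - 1L, b - 1L, an - 1L, d - 1L)] <-
        dihedral_angle(g, a, b, an, d)
    }
  }
  structure(list(connectivity = connectivity, bonds = bonds,
                 angles = angles, dihedrals = dihedrals),
            class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat("zmatrix:", length(x$bonds), "bonds,", length(x$angles), "angles,",
      length(x$dihedrals), "dihedrals\n")
  invisible(x)
}

#' Flatten a Z-matrix into a feature vector
#' @param z a \code{zmatrix}.
#' @return named numeric vector (bonds, then angles, then dihedrals).
#' @export
zmatrix_vector <- function(z) {
  stopifnot(inherits(z, "zmatrix"))
  c(z$bonds, z$angles, z$dihedrals)
}

#' Rebuild Cartesian coordinates from a Z-matrix
#'
#' Natural-extension reference-frame (NeRF) placement: atom 1 at the origin,
#' atom 2 along +x, atom 3 in the xy-plane, subsequent atoms from their
#' bond/angle/dihedral entries.  The result reproduces the generating
#' geometry up to a rigid motion, so \code{zmatrix()} of the rebuilt
#' coordinates equals the input record.
#'
#' @param z a \code{zmatrix} built with sequential connectivity.
#' @param labels element labels for the rebuilt \code{geometry}.
#' @return a \code{geometry}.
#' @export
zmatrix_to_cartesian <- function(z, labels = NULL) {
  stopifnot(inherits(z, "zmatrix"))
  conn <- z$connectivity
  n <- nrow(conn)
  if (is.null(labels)) labels <- rep("X", n)
  xyz <- matrix(0, n, 3)
  bonds <- z$bonds; angles <- z$angles; dihedrals <- z$dihedrals
  bi <- ai <- di <- 0L
  for (r in seq_len(n)) {
    a <- conn$atom[r]
    if (r == 1L) next
    bi <- bi + 1L
    rb <- bonds[bi]
    b <- conn$bond[r]
    if (r == 2L) {
      xyz[a, ] <- xyz[b, ] + c(rb, 0, 0)
      next
    }
    ai <- ai + 1L
    theta <- angles[ai] * pi / 180
    c_ <- conn$angle[r]
    if (r == 3L) {
      u <- xyz[c_, ] - xyz[b, ]
      u <- u / sqrt(sum(u^2))
      # place in the xy-plane
      perp <- c(-u[2], u[1], 0)
      if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      xyz[a, ] <- xyz[b, ] + rb * (cos(theta) * u + sin(theta) * perp)
      next
    }
    di <- di + 1L
    phi <- dihedrals[di] * pi / 180
    d_ <- conn$dihedral[r]
    # NeRF: frame at atom b from the b<-c<-d chain
    bc <- xyz[b, ] - xyz[c_, ]
    cd <- xyz[c_, ] - xyz[d_, ]
    bch <- bc / sqrt(sum(bc^2))
    nv <- .cross3(cd, bch)
    if (sum(nv^2) < 1e-20)
      stop("degenerate (collinear) reference frame at atom ", a)
    nv <- nv / sqrt(sum(nv^2))
    mv <- .cross3(nv, bch)
    d2 <- c(-rb * cos(theta), rb * sin(theta) * cos(phi),
            rb * sin(theta) * sin(phi))
    xyz[a, ] <- xyz[b, ] + d2[1] * bch + d2[2] * mv + d2[3] * nv
  }
  geometry(labels, xyz)
}

#' Wrap an angular difference to the smallest signed value
#' @param delta difference in degrees.
#' @return equivalent angle in (-180, 180].
#' @export
wrap_angle <- function(delta) {
  w <- (delta + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Delta Z-matrix with optional bounded transforms
#'
#' Differences a Z-matrix against a reference sharing the same
#' connectivity.  Bond deltas are in Angstrom; angular deltas are wrapped to
#' the smallest signed difference in (-180, 180] degrees.  The optional
#' nonlinear transforms operate on scaled deltas (bonds in Angstrom,
#' angles/dihedrals converted to radians so that +/-180 deg maps to +/-pi
#' rather than saturating): \code{tanh} applies the hyperbolic tangent,
#' \code{sig} the logistic function 1/(1+exp(-x)).
#'
#' @param z,z_ref \code{zmatrix} objects with identical connectivity.
#' @param transform one of \code{"none"}, \code{"tanh"}, \code{"sig"}.
#' @return named numeric feature vector (bond deltas, angle deltas,
#'   dihedral deltas, in that order).
#' @export
delta_zmatrix <- function(z, z_ref, transform = c("none", "tanh", "sig")) {
  transform <- match.arg(transform)
  stopifnot(inherits(z, "zmatrix"), inherits(z_ref, "zmatrix"))
  if (!identical(z$connectivity, z_ref$connectivity))
    stop("connectivity mismatch between z and z_ref")
  db <- z$bonds - z_ref$bonds
  da <- wrap_angle(z$angles - z_ref$angles)
  dd <- wrap_angle(z$dihedrals - z_ref$dihedrals)
  if (transform == "none") return(c(db, da, dd))
  x <- c(db, da * pi / 180, dd * pi / 180)
  out <- switch(transform, tanh = tanh(x), sig = 1 / (1 + exp(-x)))
  names(out) <- c(names(db), names(da), names(dd))
  out
}
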