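# Cremer-Pople generalized ring-puckering coordinates.

#' Cremer-Pople ring-puckering parameters
#'
#' Quantifies the deviation of an N-membered ring from planarity using the
#' standard construction: the ring is translated to its geometric centre, a
#' unique mean plane is defined through the two lattice vectors
#' R' = sum_j r_j sin(2 pi j / N) and R'' = sum_j r_j cos(2 pi j / N), and
#' the out-of-plane displacements z_j = r_j . n (n the unit normal) are
#' decomposed into puckering amplitudes q_m and phase angles phi_m
#' (m = 2 .. floor((N-1)/2)) by discrete Fourier sums; even rings carry the
#' extra single coordinate q_{N/2}.  This yields the N - 3 independent
#' puckering coordinates; the total amplitude is Q = sqrt(sum z_j^2).  For
#' six-membered rings the parameters reduce to the familiar triple
#' (Q, theta, phi) with cos(theta) = q_3 / Q and phi = phi_2, placing
#' chairs at theta = 0 or 180 degrees and boats/twist-boats on the equator.
#'
#' Atom index 1 of \code{ring_atoms} defines the phase origin j = 0.
#'
#' @param g a \code{geometry}.
#' @param ring_atoms ordered 1-based atom indices around the ring (N >= 4).
#' @return object of class \code{puckering}: list with \code{z}
#'   (displacements, Angstrom), \code{q} and \code{phi} (named amplitudes in
#'   Angstrom / phases in degrees), \code{Q} (Angstrom), and for six-membered
#'   rings \code{theta} and \code{phi_angle} (degrees).  \code{params} holds
#'   the N - 3 independent coordinates as a named vector.
#' @examples
#' hexagon <- geometry(rep("C", 6), t(vapply(0:5, function(j)
#'   1.4 * c(cos(pi * j / 3), sin(pi * j / 3), 0), numeric(3))))
#' cremer_pople(hexagon, 1:6)$Q  # 0: planar
#' @export
cremer_pople <- function(g, ring_atoms) {
  stopifnot(inherits(g, "geometry"))
  N <- length(ring_atoms)
  if (N < 4L) stop("ring must have at least 4 atoms")
  R <- g$coords[ring_atoms, , drop = FALSE]
  R <- sweep(R, 2, colMeans(R))
  j <- seq_len(N) - 1L
  Rp <- colSums(R * sin(2 * pi * j / N))
  Rpp <- colSums(R * cos(2 * pi * j / N))
  nrm <- .cross3(Rp, Rpp)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) stop("degenerate (collinear) ring: mean plane undefined")
  nrm <- nrm / nn
  z <- as.numeric(R %*% nrm)

  m_max <- floor((N - 1) / 2)
  ms <- if (m_max >= 2) 2:m_max else integer(0)
  q <- numeric(0); phi <- numeric(0)
  for (m in ms) {
    cm <- sqrt(2 / N) * sum(z * cos(2 * pi * m * j / N))
    sm <- -sqrt(2 / N) * sum(z * sin(2 * pi * m * j / N))
    q[paste0("q", m)] <- sqrt(cm^2 + sm^2)
    phi[paste0("phi", m)] <- (atan2(sm, cm) * 180 / pi) %% 360
  }
  if (N %% 2 == 0) {
    q[paste0("q", N / 2)] <-
      sqrt(1 / N) * sum(z * cos(pi * j))  # (-1)^j weights
  }
  Q <- sqrt(sum(z^2))
  params <- as.numeric(rbind(q[paste0("q", ms)], phi[paste0("phi", ms)]))
  names(params) <- as.vector(rbind(paste0("q", ms), paste0("phi", ms)))
  if (N %% 2 == 0) params[paste0("q", N / 2)] <- q[paste0("q", N / 2)]

  out <- list(z = z, q = q, phi = phi, Q = Q, params = params, N = N)
  if (N == 6L) {
    theta <- if (Q > 1e-12) acos(max(-1, min(1, q[["q3"]] / Q))) * 180 / pi
             else 0
    out$theta <- theta
    out$phi_angle <- if ("phi2" %in% names(phi)) phi[["phi2"]] else 0
    out$params <- c(Q = Q, theta = out$theta, phi = out$phi_angle)
  }
  structure(out, class = "puckering")
}

#' @export
print.puckering <- function(x, ...) {
  cat("Cremer-Pople puckering,", x$N, "-membered ring: Q =",
      signif(x$Q, 6), "A")
  if (!is.null(x$theta))
    cat(", theta =", signif(x$theta, 6), "deg, phi =",
        signif(x$phi_angle, 6), "deg")
  cat("\n")
  invisible(x)
}
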