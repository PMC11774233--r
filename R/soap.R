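# SOAP (Smooth Overlap of Atomic Positions) power-spectrum descriptor.
#
# Each atomic environment is the Gaussian-smeared density of its neighbours
# of species Z within r_cut,
#     rho_Z(r) = sum_i exp(-|r - r_i|^2 / (2 sigma^2)),
# expanded in an orthonormal radial basis g_n(r) times real spherical
# harmonics Y_lm:
#     c^Z_nlm = <g_n Y_lm | rho_Z>.
# The rotationally invariant partial power spectrum combines coefficients of
# two species channels:
#     p(Z1, Z2, n, n', l) = pi sqrt(8 / (2l + 1)) sum_m c^Z1_nlm c^Z2_n'lm.
#
# The angular integral over each neighbour Gaussian is done analytically via
# the plane-wave-like expansion
#     exp(-a |r - ri|^2) = exp(-a (r^2 + ri^2)) *
#         4 pi sum_lm i_l(2 a r ri) Y_lm(rhat) Y_lm(rihat),
# with i_l the modified spherical Bessel function, leaving one radial
# quadrature per (n, l, neighbour distance).  The radial basis is the
# orthonormalised polynomial set g_n built from (r_cut - r)^(n+2), a common
# choice for molecular SOAP.

#' SOAP descriptor parameters
#'
#' @param species character vector of element symbols the descriptor
#'   supports (order fixes the feature layout).
#' @param r_cut radial cutoff, Angstrom.
#' @param n_max number of radial basis functions (>= 1).
#' @param l_max maximum spherical-harmonic degree (>= 0).
#' @param sigma_atom width of the atomic Gaussians, Angstrom.
#' @param aggregation \code{"averaged"} (mean over atomic centres; one
#'   molecule-level vector) or \code{"per-atom"} (concatenated per centre).
#' @param n_quad Gauss-Legendre points for the radial quadrature.
#' @return object of class \code{soap_params}.
#' @export
soap_params <- function(species, r_cut = 6.0, n_max = 8L, l_max = 6L,
                        sigma_atom = 0.5,
                        aggregation = c("averaged", "per-atom"),
                        n_quad = 120L) {
  aggregation <- match.arg(aggregation)
  if (n_max < 1L) stop("n_max must be >= 1")
  if (l_max < 0L) stop("l_max must be >= 0")
  if (r_cut <= 0) stop("r_cut must be > 0")
  if (sigma_atom <= 0) stop("sigma_atom must be > 0")
  structure(list(species = unique(as.character(species)), r_cut = r_cut,
                 n_max = as.integer(n_max), l_max = as.integer(l_max),
                 sigma_atom = sigma_atom, aggregation = aggregation,
                 n_quad = as.integer(n_quad)),
            class = "soap_params")
}

# Orthonormalisation weights for the polynomial radial basis:
# phi_n(r) = ((r_cut - r)/r_cut)^(n+2) (cutoff-normalised for conditioning),
# S_mn = int_0^rcut phi_m phi_n r^2 dr (closed form), g = S^(-1/2) phi.
.soap_radial_weights <- function(n_max, r_cut) {
  S <- matrix(0, n_max, n_max)
  for (m in 1:n_max) for (n in 1:n_max) {
    p <- m + n + 4
    S[m, n] <- r_cut^3 * 2 / ((p + 1) * (p + 2) * (p + 3))
  }
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("radial overlap matrix not positive definite; lower n_max")
  e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
}

# g_n(r) evaluated at radial quadrature nodes: (n_max x n_r) matrix.
.soap_radial_basis <- function(r, n_max, r_cut) {
  W <- .soap_radial_weights(n_max, r_cut)
  phi <- t(vapply(1:n_max, function(n) ((r_cut - r) / r_cut)^(n + 2),
                  numeric(length(r))))
  W %*% phi
}

# Real spherical harmonics Y_lm for l = 0..l_max at unit vectors
# (rows of u).  Returns list by l of (n_points x (2l+1)) matrices with
# columns m = -l..l.  Uses pracma::legendre (Condon-Shortley included).
.real_sph_harm <- function(u, l_max) {
  ct <- pmax(-1, pmin(1, u[, 3]))
  az <- atan2(u[, 2], u[, 1])
  out <- vector("list", l_max + 1)
  for (l in 0:l_max) {
    Y <- matrix(0, nrow(u), 2 * l + 1)
    P <- if (l == 0) matrix(1, 1, length(ct)) else pracma::legendre(l, ct)
    for (m in 0:l) {
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  factorial(l - m) / factorial(l + m))
      Plm <- P[m + 1, ]
      if (m == 0) {
        Y[, l + 1] <- Nlm * Plm
      } else {
        Y[, l + 1 + m] <- sqrt(2) * Nlm * Plm * cos(m * az)
        Y[, l + 1 - m] <- sqrt(2) * Nlm * Plm * sin(m * az)
      }
    }
    out[[l + 1]] <- Y
  }
  out
}

# Modified spherical Bessel i_l(x) scaled by exp(-s): returns
# i_l(x) * exp(-s) computed stably via besselI(..., expon.scaled).
.scaled_sph_bessel_i <- function(x, l, s) {
  out <- numeric(length(x))
  small <- x < 1e-12
  if (any(small)) out[small] <- if (l == 0) exp(-s[small]) else 0
  big <- !small
  if (any(big)) {
    out[big] <- sqrt(pi / (2 * x[big])) *
      besselI(x[big], l + 0.5, expon.scaled = TRUE) * exp(x[big] - s[big])
  }
  out
}

# Expansion coefficients c^Z_nlm for one centre: list by l of
# (n_max x (2l+1)) matrices, one list per species.
.soap_coefficients <- function(coords, labels, centre, params) {
  a <- 1 / (2 * params$sigma_atom^2)
  gl <- pracma::gaussLegendre(params$n_quad, 0, params$r_cut)
  r <- gl$x; w <- gl$w
  G <- .soap_radial_basis(r, params$n_max, params$r_cut)  # n_max x n_r
  wr2 <- w * r^2

  rel <- sweep(coords, 2, coords[centre, ])
  di <- sqrt(rowSums(rel^2))
  keep <- which(di <= params$r_cut)
  res <- list()
  for (Z in params$species) {
    idx <- keep[labels[keep] == Z]
    cz <- lapply(0:params$l_max, function(l)
      matrix(0, params$n_max, 2 * l + 1))
    for (i in idx) {
      ri <- di[i]
      if (ri < 1e-10) {
        # neighbour at the centre: only l = 0 survives
        rad <- exp(-a * r^2)
        I0 <- as.numeric(G %*% (wr2 * rad))
        cz[[1]][, 1] <- cz[[1]][, 1] + 4 * pi * (1 / sqrt(4 * pi)) * I0
        next
      }
      u <- matrix(rel[i, ] / ri, 1, 3)
      Yl <- .real_sph_harm(u, params$l_max)
      for (l in 0:params$l_max) {
        bess <- .scaled_sph_bessel_i(2 * a * r * ri, l, a * (r^2 + ri^2))
        Inl <- as.numeric(G %*% (wr2 * bess))
        cz[[l + 1]] <- cz[[l + 1]] +
          4 * pi * Inl %o% Yl[[l + 1]][1, ]
      }
    }
    res[[Z]] <- cz
  }
  res
}

# Stable feature names for the power spectrum layout.
.soap_feature_names <- function(params) {
  sp <- params$species
  nm <- character(0)
  for (zi in seq_along(sp)) for (zj in zi:length(sp)) {
    for (l in 0:params$l_max) {
      for (n in 1:params$n_max) {
        n2_start <- if (zi == zj) n else 1L
        for (n2 in n2_start:params$n_max) {
          nm <- c(nm, sprintf("P_%s_%s_n%d_n%d_l%d", sp[zi], sp[zj], n, n2, l))
        }
      }
    }
  }
  nm
}

#' SOAP power-spectrum descriptor of a geometry
#'
#' Computes the rotation- and translation-invariant partial power spectrum
#' for every atomic centre and either averages over centres (one
#' molecule-level vector, the default) or concatenates them.
#'
#' @param g a \code{geometry}; every element must appear in
#'   \code{params$species}.
#' @param params a \code{\link{soap_params}} object.
#' @return named numeric vector (averaged) or matrix with one row per atom
#'   (per-atom aggregation).
#' @export
soap_power_spectrum <- function(g, params) {
  stopifnot(inherits(g, "geometry"), inherits(params, "soap_params"))
  outside <- setdiff(unique(g$labels), params$species)
  if (length(outside))
    stop("elements outside the species set: ", paste(outside, collapse = ", "))
  sp <- params$species
  nm <- .soap_feature_names(params)
  pref <- pi * sqrt(8 / (2 * (0:params$l_max) + 1))
  per_atom <- matrix(0, n_atoms(g), length(nm))
  for (centre in seq_len(n_atoms(g))) {
    cz <- .soap_coefficients(g$coords, g$labels, centre, params)
    v <- numeric(length(nm)); pos <- 0L
    for (zi in seq_along(sp)) for (zj in zi:length(sp)) {
      c1 <- cz[[sp[zi]]]; c2 <- cz[[sp[zj]]]
      for (l in 0:params$l_max) {
        M <- c1[[l + 1]] %*% t(c2[[l + 1]])  # n_max x n_max over m-sum
        for (n in 1:params$n_max) {
          n2_start <- if (zi == zj) n else 1L
          for (n2 in n2_start:params$n_max) {
            pos <- pos + 1L
            v[pos] <- pref[l + 1] * M[n, n2]
          }
        }
      }
    }
    per_atom[centre, ] <- v
  }
  colnames(per_atom) <- nm
  if (params$aggregation == "averaged") colMeans(per_atom) else per_atom
}
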