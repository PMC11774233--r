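# Synthetic trajectory-ensemble generator.  Produces the same on-disk layout
# the ingestion module reads (TRAJ<k>/dyn.xyz + properties.csv + geom.xyz at
# the root) with exactly known, kinematic structure: a harmonic stretch of
# one bond, an optional torsion oscillation, latent conformer classes
# encoded as static torsion offsets, hop events flagged at the per-cycle
# stretch maxima, and an energy gap linear in the stretch.  Because the
# trajectories are closed-form rather than integrated dynamics, every
# pipeline stage can be validated against exact ground truth.

#' Molecular templates for the generator
#'
#' \code{fulvene_like}: a planar five-membered carbon ring with an exocyclic
#' CH2 group (12 atoms, C6H6), the minimal motif exhibiting the
#' bond-stretch + methylene-rotation phase space typical of ultrafast
#' ring-system photodynamics.  \code{ring6_planar}: ideal planar hexagon,
#' side 1.4 Angstrom (zero puckering by construction).  \code{chain}: an
#' n-atom helical carbon chain with well-defined dihedrals.
#'
#' @param name one of \code{"fulvene_like"}, \code{"ring6_planar"},
#'   \code{"chain"}.
#' @param n chain length (for \code{"chain"} only; >= 2).
#' @return a \code{geometry}.
#' @export
make_template <- function(name = c("fulvene_like", "ring6_planar", "chain"),
                          n = 4L) {
  name <- match.arg(name)
  if (name == "ring6_planar") {
    j <- 0:5
    return(geometry(rep("C", 6),
                    cbind(1.4 * cos(pi * j / 3), 1.4 * sin(pi * j / 3), 0)))
  }
  if (name == "chain") {
    if (n < 2L) stop("chain needs n >= 2")
    i <- seq_len(n) - 1L
    # gentle helix: every dihedral well defined
    return(geometry(rep("C", n),
                    cbind(1.0 * cos(0.8 * i), 1.0 * sin(0.8 * i), 0.9 * i)))
  }
  # fulvene_like: C1..C5 ring, C6 exocyclic on C1, H on C2..C5, 2 H on C6
  rr <- 1.4 / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  ring <- cbind(rr * cos(ang), rr * sin(ang), 0)
  c6 <- ring[1, ] + c(1.35, 0, 0)
  h_ring <- ring[2:5, ] * ((rr + 1.08) / rr)
  h6a <- c6 + 1.08 * c(cos(pi / 3), sin(pi / 3), 0)
  h6b <- c6 + 1.08 * c(cos(-pi / 3), sin(-pi / 3), 0)
  geometry(c(rep("C", 6), rep("H", 6)),
           rbind(ring, c6, h_ring, h6a, h6b))
}

# Rodrigues rotation of points about the axis through `origin` with unit
# direction `u` by `angle` radians.
.rotate_about_axis <- function(xyz, origin, u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

#' Configuration for the synthetic-ensemble generator
#'
#' Defaults emulate, at desk scale, a small surface-hopping ensemble of a
#' fulvene-like molecule: 10 trajectories of 20 fs at a 0.1 fs step, a
#' 0.25 Angstrom stretch of the exocyclic C-C bond with a 10 fs period,
#' a +/-15 degree methylene torsion active in 30 percent of trajectories,
#' three latent conformer classes given by static torsion offsets of
#' 0 / 60 / 120 degrees in proportions 0.4 / 0.4 / 0.2 (the rotated class
#' deliberately smallest), hops flagged within 0.002 Angstrom of the
#' per-cycle stretch maximum, and a gap linear in the stretch
#' (3.8 eV intercept, -6 eV/Angstrom slope, 0.1 eV Gaussian noise).
#'
#' @param template template name (see \code{\link{make_template}}).
#' @param n_trajs number of trajectories.
#' @param n_steps frames per trajectory.
#' @param dt time step, fs.
#' @param stretch list: \code{pair} (1-based atom indices of the stretched
#'   bond; the second atom's rigid group moves), \code{amplitude} (Angstrom),
#'   \code{period} (fs).
#' @param torsion list: \code{amplitude} (deg), \code{period} (fs),
#'   \code{fraction} of trajectories with the oscillation active.
#' @param classes list: \code{proportions} (sum to 1) and
#'   \code{torsion_offsets} (static offsets, deg, one per class); optional
#'   \code{gap_shift} (eV per class, default 0).
#' @param hop_delta hop flagged when the noiseless stretch is within this
#'   distance (Angstrom) of its maximum.
#' @param gap list: \code{g0} intercept (eV), \code{slope} (eV/Angstrom,
#'   applied to the signed stretch displacement), \code{sigma} noise (eV).
#' @param jitter isotropic Gaussian coordinate noise, Angstrom.
#' @param seed integer seed governing all randomness.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(template = "fulvene_like", n_trajs = 10L,
                         n_steps = 201L, dt = 0.1,
                         stretch = list(pair = c(1L, 6L), amplitude = 0.25,
                                        period = 10),
                         torsion = list(amplitude = 15, period = 15,
                                        fraction = 0.3),
                         classes = list(proportions = c(0.4, 0.4, 0.2),
                                        torsion_offsets = c(0, 60, 120)),
                         hop_delta = 0.002,
                         gap = list(g0 = 3.8, slope = -6, sigma = 0.1),
                         jitter = 0.01, seed = 1L) {
  stopifnot(dt > 0, n_trajs >= 1, n_steps >= 1,
            stretch$amplitude >= 0, torsion$amplitude >= 0)
  if (abs(sum(classes$proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (length(classes$proportions) != length(classes$torsion_offsets))
    stop("one torsion offset per class required")
  if (is.null(classes$gap_shift))
    classes$gap_shift <- rep(0, length(classes$proportions))
  structure(list(template = template, n_trajs = as.integer(n_trajs),
                 n_steps = as.integer(n_steps), dt = dt, stretch = stretch,
                 torsion = torsion, classes = classes, hop_delta = hop_delta,
                 gap = gap, jitter = jitter, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic trajectory ensemble on disk
#'
#' Writes \code{TRAJ1..TRAJn} directories (concatenated XYZ + property CSV)
#' plus the reference \code{geom.xyz} and a \code{truth.json} with the
#' planted per-trajectory class labels and hop events.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param out_dir output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
simulate_ensemble <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(cfg$seed)
  template <- make_template(cfg$template)
  write_xyz_trajectory(file.path(out_dir, "geom.xyz"), 0, list(template))

  # plant classes with exact proportional counts (largest-remainder
  # rounding), randomly permuted over trajectories, so the realised class
  # structure matches the configured proportions even for small ensembles
  n_class <- length(cfg$classes$proportions)
  counts <- diff(c(0L, round(cumsum(cfg$classes$proportions) * cfg$n_trajs)))
  traj_class <- sample(rep.int(seq_len(n_class), counts))
  torsion_active <- stats::runif(cfg$n_trajs) < cfg$torsion$fraction
  stretch_phase <- stats::runif(cfg$n_trajs, 0, 2 * pi)

  i_anchor <- cfg$stretch$pair[1]
  i_rotor <- cfg$stretch$pair[2]
  axis <- template$coords[i_rotor, ] - template$coords[i_anchor, ]
  rotor_atoms <- .rigid_group(template, i_anchor, i_rotor)

  times <- (seq_len(cfg$n_steps) - 1L) * cfg$dt
  hops <- list()
  for (tr in seq_len(cfg$n_trajs)) {
    tdir <- file.path(out_dir, paste0("TRAJ", tr))
    dir.create(tdir, showWarnings = FALSE)
    geoms <- vector("list", cfg$n_steps)
    s_t <- cfg$stretch$amplitude *
      sin(2 * pi * times / cfg$stretch$period + stretch_phase[tr])
    tors_t <- rep(cfg$classes$torsion_offsets[traj_class[tr]], cfg$n_steps)
    if (torsion_active[tr])
      tors_t <- tors_t +
        cfg$torsion$amplitude * sin(2 * pi * times / cfg$torsion$period)
    for (f in seq_len(cfg$n_steps)) {
      xyz <- template$coords
      if (abs(tors_t[f]) > 1e-12)
        xyz[rotor_atoms, ] <- .rotate_about_axis(
          xyz[rotor_atoms, , drop = FALSE], template$coords[i_anchor, ],
          axis, tors_t[f] * pi / 180)
      if (s_t[f] != 0) {
        shift <- s_t[f] * axis / sqrt(sum(axis^2))
        xyz[rotor_atoms, ] <- sweep(xyz[rotor_atoms, , drop = FALSE], 2,
                                    shift, "+")
      }
      if (cfg$jitter > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = cfg$jitter),
                            nrow(xyz), 3)
      geoms[[f]] <- geometry(template$labels, xyz)
    }
    write_xyz_trajectory(file.path(tdir, "dyn.xyz"), times, geoms)

    # hop rule: within hop_delta of the per-cycle stretch maximum
    is_max <- cfg$stretch$amplitude > 0 &
      (cfg$stretch$amplitude - s_t) <= cfg$hop_delta
    state <- integer(cfg$n_steps)
    hf <- hb <- integer(cfg$n_steps)
    cur <- 2L
    for (f in seq_len(cfg$n_steps)) {
      if (is_max[f]) {
        if (cur == 2L) { hf[f] <- 1L; cur <- 1L } else { hb[f] <- 1L; cur <- 2L }
      }
      state[f] <- cur
    }
    gap <- cfg$gap$g0 + cfg$gap$slope * s_t +
      cfg$classes$gap_shift[traj_class[tr]] +
      stats::rnorm(cfg$n_steps, sd = cfg$gap$sigma)
    s1 <- -230.0 + stats::rnorm(cfg$n_steps, sd = 1e-4)
    pop2 <- exp(-times / 30)
    props <- data.frame(traj = tr, time = times, State = state,
                        Total_Energy = -229.85, S1 = s1,
                        S2 = s1 + gap / 27.211386,
                        DE21 = gap, Hops_S21 = hf, Hops_S12 = hb,
                        Pop1 = 1 - pop2, Pop2 = pop2)
    utils::write.csv(props, file.path(tdir, "properties.csv"),
                     row.names = FALSE, quote = FALSE)
    if (any(is_max))
      hops[[tr]] <- data.frame(traj = tr, time = times[is_max],
                               direction = ifelse(hf[is_max] == 1,
                                                  "forward", "back"))
  }
  truth <- list(n_trajs = cfg$n_trajs, n_steps = cfg$n_steps, dt = cfg$dt,
                traj_class = traj_class,
                torsion_active = torsion_active,
                stretch_pair = cfg$stretch$pair,
                stretch_amplitude = cfg$stretch$amplitude,
                hops = if (length(hops)) do.call(rbind, hops)
                       else data.frame(traj = integer(0), time = numeric(0),
                                       direction = character(0)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Atoms rigidly attached to the rotor side of the (anchor, rotor) bond:
# connected component of the 1.8-Angstrom bond graph containing `rotor`
# after removing the anchor atom.
.rigid_group <- function(g, anchor, rotor) {
  n <- n_atoms(g)
  D <- as.matrix(stats::dist(g$coords))
  adj <- D < 1.8 & upper.tri(D, diag = FALSE)
  adj <- adj | t(adj)
  adj[anchor, ] <- FALSE; adj[, anchor] <- FALSE
  seen <- rep(FALSE, n)
  queue <- rotor
  seen[rotor] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  which(seen)
}

#' Planted ground truth of a synthetic ensemble
#'
#' @param out_dir directory written by \code{\link{simulate_ensemble}}.
#' @return list with \code{labels} (data.frame traj, time, label: the
#'   planted conformer class per frame, 1-based) and \code{hops}
#'   (data.frame traj, time, direction).
#' @export
ground_truth <- function(out_dir) {
  path <- file.path(out_dir, "truth.json")
  if (!file.exists(path)) stop("no truth.json under ", out_dir)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  times <- (seq_len(truth$n_steps) - 1L) * truth$dt
  labels <- data.frame(
    traj = rep(seq_len(truth$n_trajs), each = truth$n_steps),
    time = rep(times, truth$n_trajs),
    label = rep(truth$traj_class, each = truth$n_steps))
  hops <- as.data.frame(truth$hops)
  list(labels = labels, hops = hops,
       stretch_pair = truth$stretch_pair,
       stretch_amplitude = truth$stretch_amplitude)
}
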