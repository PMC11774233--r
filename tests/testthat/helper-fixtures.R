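# Shared fixtures, all built in code at test time.

# feature table wrapper around a plain matrix
as_ftable <- function(x, traj = 1L) {
  x <- as.matrix(x)
  cbind(data.frame(traj = traj, time = seq_len(nrow(x)) - 1), as.data.frame(x))
}

# random geometry with n atoms, coordinates ~ U(-2, 2)
random_geometry <- function(n, labels = rep("C", n)) {
  geometry(labels, matrix(stats::runif(3 * n, -2, 2), n, 3))
}

# planar hexagon, side `side`, optional out-of-plane displacements z
hexagon_geometry <- function(side = 1.4, z = rep(0, 6)) {
  j <- 0:5
  geometry(rep("C", 6), cbind(side * cos(pi * j / 3),
                              side * sin(pi * j / 3), z))
}

# small synthetic ensemble on disk; returns its directory
make_synth_dir <- function(..., seed = 11) {
  dir <- tempfile("synthens")
  simulate_ensemble(synth_config(..., seed = seed), dir)
  dir
}

# configuration with three well-separated conformer classes (static torsion
# offsets only; no torsion oscillation, modest stretch, small jitter) --
# gives >= 5 sigma between-class separation in delta-Z-matrix space
separated_config <- function(n_trajs = 12L, n_steps = 101L, seed = 11L) {
  synth_config(n_trajs = n_trajs, n_steps = n_steps,
               stretch = list(pair = c(1L, 6L), amplitude = 0.1, period = 10),
               torsion = list(amplitude = 0, period = 15, fraction = 0),
               seed = seed)
}

# planted class labels aligned with the rows of a feature table
truth_labels_for <- function(tab, truth) {
  key <- paste(tab$traj, round(tab$time, 6))
  tkey <- paste(truth$labels$traj, round(truth$labels$time, 6))
  truth$labels$label[match(key, tkey)]
}
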