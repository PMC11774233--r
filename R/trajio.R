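# Trajectory ingestion: discovery of TRAJ<k> directories, concatenated-XYZ
# geometry series, per-trajectory property tables, and assembly into one
# indexed ensemble.  On-disk layout:
#   <root>/geom.xyz                 reference geometry (single XYZ block)
#   <root>/TRAJ<k>/dyn.xyz          concatenated XYZ, comment line carries
#                                   "time = <float> fs"
#   <root>/TRAJ<k>/properties.csv   traj,time,State,Total_Energy,S1,S2,...,
#                                   DE21,Hops_S21,Hops_S12,Pop1,Pop2[,f_osc_21]

.TIME_TOL <- 1e-6

#' Discover trajectory directories
#'
#' Scans \code{root_dir} for subdirectories named \code{TRAJ<k>} that contain
#' a geometry series and returns the sorted integer ids.  Non-matching
#' directories are ignored with a message.
#'
#' @param root_dir path to the ensemble root.
#' @param geometry_file name of the geometry series file inside each
#'   trajectory directory (default \code{"dyn.xyz"}).
#' @return sorted integer vector of trajectory ids (empty if none).
#' @export
discover_trajectories <- function(root_dir, geometry_file = "dyn.xyz") {
  if (!dir.exists(root_dir))
    stop("root_dir does not exist: ", root_dir)
  entries <- list.dirs(root_dir, full.names = FALSE, recursive = FALSE)
  hits <- grepl("^TRAJ[0-9]+$", entries)
  skipped <- entries[!hits & nzchar(entries)]
  if (length(skipped))
    message("ignoring ", length(skipped), " non-trajectory directories: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  ids <- as.integer(sub("^TRAJ", "", entries[hits]))
  keep <- vapply(ids, function(k) {
    file.exists(file.path(root_dir, paste0("TRAJ", k), geometry_file))
  }, logical(1))
  sort(ids[keep])
}

#' Read a concatenated-XYZ trajectory
#'
#' Parses repeated XYZ blocks (atom-count line, comment line, atom lines).
#' The comment line must carry the frame time as \code{"time = <float> fs"};
#' if absent, frames are numbered 0, 1, 2, ... fs is assumed.
#'
#' @param path XYZ file.
#' @return list with \code{times} (numeric, fs) and \code{geometries}
#'   (list of \code{geometry}), in file order.
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  times <- numeric(0)
  geoms <- list()
  i <- 1L
  frame <- 0L
  n_ref <- NA_integer_
  while (i <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("frame ", frame, ": malformed atom count line: '", lines[i], "'")
    if (is.na(n_ref)) n_ref <- nat
    else if (nat != n_ref)
      stop("frame ", frame, ": atom count ", nat,
           " differs from first frame (", n_ref, ")")
    if (i + 1L + nat > length(lines))
      stop("frame ", frame, ": truncated block")
    comment <- lines[i + 1L]
    tm <- regmatches(comment,
                     regexec("time\\s*=\\s*(-?[0-9.eE+-]+)", comment))[[1]]
    t_fs <- if (length(tm) == 2) as.numeric(tm[2]) else as.numeric(frame - 1L)
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop("frame ", frame, ": unparseable atom line ", bad[1])
    labels <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      v
    }, numeric(3)))
    if (any(!is.finite(xyz)))
      stop("frame ", frame, ": unparseable coordinate value")
    times <- c(times, t_fs)
    geoms[[frame]] <- geometry(labels, xyz)
    i <- i + 2L + nat
  }
  list(times = times, geometries = geoms)
}

#' Write a concatenated-XYZ trajectory
#'
#' Inverse of \code{\link{read_xyz_trajectory}}; coordinates are printed with
#' 8 decimals, so a write/read round trip reproduces them to 1e-8.
#'
#' @param path output file.
#' @param times numeric frame times, fs.
#' @param geometries list of \code{geometry}, same length as \code{times}.
#' @export
write_xyz_trajectory <- function(path, times, geometries) {
  stopifnot(length(times) == length(geometries))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(times)) {
    g <- geometries[[f]]
    writeLines(as.character(n_atoms(g)), con)
    writeLines(sprintf("time = %.6f fs", times[f]), con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f", g$labels,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a single-frame reference geometry
#'
#' @param path XYZ file containing one block (e.g. \code{geom.xyz} at the
#'   ensemble root).
#' @return a \code{geometry}.
#' @export
read_reference_geometry <- function(path) {
  tr <- read_xyz_trajectory(path)
  if (length(tr$geometries) != 1L)
    warning("reference file has ", length(tr$geometries),
            " frames; using the first")
  tr$geometries[[1]]
}

.PROP_MANDATORY <- c("State", "Total_Energy", "S1")

#' Read a per-trajectory property table
#'
#' Loads \code{properties.csv} from a trajectory directory.  Mandatory
#' columns: \code{time}, \code{State}, \code{Total_Energy} and at least one
#' state energy (\code{S1}).  Hop flags \code{Hops_S21} / \code{Hops_S12}
#' (1 = hopping event at that frame, 0 = none) and populations
#' \code{Pop1}, \code{Pop2}, ... are picked up when present; missing hop
#' columns default to all-zero.
#'
#' @param traj_dir directory containing \code{properties.csv}.
#' @param file property file name.
#' @return data.frame with one row per time step, \code{time} first.
#' @export
read_properties <- function(traj_dir, file = "properties.csv") {
  path <- file.path(traj_dir, file)
  if (!file.exists(path)) stop("no property table at ", path)
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(c("time", .PROP_MANDATORY), names(df))
  if (length(missing))
    stop("property table ", path, " lacks mandatory columns: ",
         paste(missing, collapse = ", "))
  for (h in c("Hops_S21", "Hops_S12")) {
    if (!h %in% names(df)) df[[h]] <- 0L
    if (!all(df[[h]] %in% c(0, 1)))
      stop("hop flag column ", h, " must be 0/1")
  }
  pops <- grep("^Pop[0-9]+$", names(df), value = TRUE)
  for (p in pops) {
    bad <- stats::na.omit(df[[p]])
    if (any(bad < -1e-9 | bad > 1 + 1e-9))
      stop("population column ", p, " outside [0, 1]")
  }
  df[order(df$time), , drop = FALSE]
}

#' Assemble an ensemble dataset
#'
#' Inner join of geometry frames and property records on (trajectory, time)
#' with a time tolerance of 1e-6 fs.  Frames present on only one side are
#' dropped with a message; the result is sorted by (traj, time).
#'
#' @param geoms named list: for each trajectory id (as character), a list
#'   with \code{times} and \code{geometries} as returned by
#'   \code{\link{read_xyz_trajectory}}.
#' @param props named list of property data.frames keyed the same way.
#' @return an object of class \code{md_ensemble}: list with
#'   \code{index} (data.frame traj, time), \code{geometries} (list),
#'   \code{properties} (data.frame, rows aligned with index),
#'   \code{atom_labels}, \code{n_trajs}, \code{n_frames}.
#' @export
assemble_ensemble <- function(geoms, props) {
  ids <- sort(as.integer(intersect(names(geoms), names(props))))
  if (!length(ids)) stop("empty ensemble: no trajectory present on both sides")
  idx_traj <- integer(0); idx_time <- numeric(0)
  all_geoms <- list(); prop_rows <- list()
  dropped <- 0L
  atom_labels <- NULL
  for (id in ids) {
    key <- as.character(id)
    g <- geoms[[key]]; p <- props[[key]]
    for (gi in g$geometries) {
      if (is.null(atom_labels)) atom_labels <- gi$labels
      else if (!identical(gi$labels, atom_labels))
        stop("trajectory ", id, ": atom labels differ across frames")
    }
    # tolerance join on time
    match_idx <- vapply(g$times, function(t) {
      j <- which(abs(p$time - t) <= .TIME_TOL)
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
    keep <- which(!is.na(match_idx))
    dropped <- dropped + (length(g$times) - length(keep)) +
      (nrow(p) - length(unique(match_idx[keep])))
    ord <- keep[order(g$times[keep])]
    idx_traj <- c(idx_traj, rep(id, length(ord)))
    idx_time <- c(idx_time, g$times[ord])
    all_geoms <- c(all_geoms, g$geometries[ord])
    prop_rows[[key]] <- p[match_idx[ord], , drop = FALSE]
  }
  if (!length(idx_traj)) stop("empty ensemble: no frame survived the join")
  if (dropped > 0L)
    message("assemble_ensemble: dropped ", dropped,
            " unmatched frames/records")
  properties <- do.call(rbind, prop_rows)
  rownames(properties) <- NULL
  properties$time <- idx_time
  properties <- cbind(traj = idx_traj,
                      properties[, c("time",
                                     setdiff(names(properties),
                                             c("traj", "time")))])
  structure(list(index = data.frame(traj = idx_traj, time = idx_time),
                 geometries = all_geoms,
                 properties = properties,
                 atom_labels = atom_labels,
                 n_trajs = length(ids),
                 n_frames = length(idx_traj)),
            class = "md_ensemble")
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat("md_ensemble:", x$n_frames, "frames from", x$n_trajs, "trajectories;",
      length(x$atom_labels), "atoms (",
      paste(unique(x$atom_labels), collapse = " "), ")\n")
  invisible(x)
}

#' Load a full ensemble from disk
#'
#' Convenience wrapper: discovers trajectories under \code{root_dir}, reads
#' each geometry series and property table, and assembles the ensemble.
#'
#' @inheritParams discover_trajectories
#' @param property_file property table file name inside each trajectory
#'   directory.
#' @return an \code{md_ensemble}.
#' @export
load_ensemble <- function(root_dir, geometry_file = "dyn.xyz",
                          property_file = "properties.csv") {
  ids <- discover_trajectories(root_dir, geometry_file)
  if (!length(ids)) stop("no trajectories found under ", root_dir)
  geoms <- list(); props <- list()
  for (id in ids) {
    tdir <- file.path(root_dir, paste0("TRAJ", id))
    geoms[[as.character(id)]] <- read_xyz_trajectory(
      file.path(tdir, geometry_file))
    props[[as.character(id)]] <- read_properties(tdir, property_file)
  }
  assemble_ensemble(geoms, props)
}

#' Select one frame from an ensemble
#'
#' @param ens an \code{md_ensemble}.
#' @param traj trajectory id.
#' @param time frame time, fs (matched within 1e-6 fs).
#' @return the stored \code{geometry}.
#' @export
select_frame <- function(ens, traj, time) {
  stopifnot(inherits(ens, "md_ensemble"))
  in_traj <- ens$index$traj == traj
  if (!any(in_traj)) stop("no trajectory ", traj, " in ensemble")
  dt <- abs(ens$index$time - time)
  hit <- which(in_traj & dt <= .TIME_TOL)
  if (!length(hit)) {
    nearest <- ens$index$time[in_traj][which.min(dt[in_traj])]
    stop("no frame at (", traj, ", ", time, "); nearest available time is ",
         nearest, " fs")
  }
  ens$geometries[[hit[1]]]
}

#' Write an indexed feature/property table as CSV
#'
#' RFC-4180 CSV with a header row; index columns \code{traj} and \code{time}
#' come first and floating-point values are printed with 6 decimals, so a
#' write/read round trip is the identity to 1e-6.
#'
#' @param table data.frame whose first columns are \code{traj}, \code{time}.
#' @param path output file.
#' @export
write_dataset_csv <- function(table, path) {
  if (!all(c("traj", "time") %in% names(table)[1:2]))
    stop("table must carry the (traj, time) index columns first")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]]) && names(out)[j] != "traj")
      out[[j]] <- formatC(out[[j]], format = "f", digits = 6)
  }
  ok <- tryCatch({
    data.table::fwrite(out, path, quote = "auto", row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read back a dataset CSV written by \code{write_dataset_csv}
#'
#' @param path CSV file.
#' @return data.frame with numeric columns restored.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as.data.frame(data.table::fread(path))
}
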