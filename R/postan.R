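# Postprocessing analytics: Kabsch-superposed RMSD against a reference
# geometry, hop / non-hop frame partitioning, and per-cluster descriptive
# statistics of electronic properties.

#' RMSD between two geometries (optional Kabsch superposition)
#'
#' With \code{align = TRUE} (default) both geometries are centred and the
#' optimal proper rotation (SVD-based, determinant-corrected so reflections
#' are disallowed) is applied before computing
#' RMSD = sqrt(mean_i |r_i - r'_i|^2).  All atoms are weighted equally.
#'
#' @param g,ref \code{geometry} objects with identical atom count and label
#'   sequence.
#' @param align superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(g, ref, align = TRUE) {
  stopifnot(inherits(g, "geometry"), inherits(ref, "geometry"))
  if (!identical(g$labels, ref$labels))
    stop("atom labels / order differ between the two geometries")
  A <- g$coords; B <- ref$coords
  if (align) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
    H <- t(A) %*% B
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    A <- A %*% t(R)
  }
  sqrt(mean(rowSums((A - B)^2)))
}

#' RMSD of every ensemble frame against a reference
#'
#' @param ens an \code{md_ensemble}.
#' @param ref reference \code{geometry} (e.g. the ground-state minimum from
#'   \code{geom.xyz}).
#' @param align superpose each frame first (default TRUE).
#' @return data.frame traj, time, rmsd (one row per frame), suitable for
#'   histogramming the conformational spread of the ensemble.
#' @export
rmsd_series <- function(ens, ref, align = TRUE) {
  stopifnot(inherits(ens, "md_ensemble"))
  vals <- vapply(ens$geometries, kabsch_rmsd, numeric(1),
                 ref = ref, align = align)
  data.frame(traj = ens$index$traj, time = ens$index$time, rmsd = vals)
}

#' Partition ensemble frames into hopping and non-hopping sets
#'
#' A frame is a hopping geometry iff its forward (\code{Hops_S21}) or
#' backward (\code{Hops_S12}) flag is set; the partition is exhaustive and
#' disjoint.  Directional subsets are returned too, since forward and back
#' hops are often analysed separately.
#'
#' @param ens an \code{md_ensemble} whose property table carries the hop
#'   flag columns.
#' @return list with logical vector \code{is_hop} plus data.frames
#'   \code{hop}, \code{non_hop}, \code{hop_forward}, \code{hop_back}
#'   (rows of the property table).
#' @export
hop_partition <- function(ens) {
  stopifnot(inherits(ens, "md_ensemble"))
  p <- ens$properties
  if (!all(c("Hops_S21", "Hops_S12") %in% names(p)))
    stop("hop flag columns missing from the property table")
  fwd <- p$Hops_S21 == 1
  bwd <- p$Hops_S12 == 1
  is_hop <- fwd | bwd
  list(is_hop = is_hop,
       hop = p[is_hop, , drop = FALSE],
       non_hop = p[!is_hop, , drop = FALSE],
       hop_forward = p[fwd, , drop = FALSE],
       hop_back = p[bwd, , drop = FALSE])
}

#' Per-cluster descriptive statistics of selected properties
#'
#' Groups a property table by cluster label and reports mean, median and
#' population (ddof 0) standard deviation for each requested property,
#' together with the cluster sizes.  This is the step that exposes, e.g.,
#' which cluster concentrates the hopping events or has the small energy
#' gaps.
#'
#' @param props data.frame of per-frame properties (rows aligned with
#'   \code{labels}).
#' @param labels integer cluster label per row (0-based).
#' @param properties character vector of property column names.
#' @return data.frame with columns label, property, mean, median, std,
#'   count (class \code{cluster_summary}).
#' @export
cluster_statistics <- function(props, labels,
                               properties = c("DE21", "Hops_S21",
                                              "Hops_S12")) {
  if (nrow(props) != length(labels))
    stop("labels length (", length(labels), ") != property rows (",
         nrow(props), ")")
  missing <- setdiff(properties, names(props))
  if (length(missing))
    stop("requested properties absent from the table: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (lab in sort(unique(labels))) {
    rows <- props[labels == lab, , drop = FALSE]
    for (pr in properties) {
      v <- rows[[pr]]
      out[[length(out) + 1L]] <- data.frame(
        label = lab, property = pr,
        mean = mean(v), median = stats::median(v),
        std = sqrt(mean((v - mean(v))^2)),
        count = nrow(rows))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cluster_summary", "data.frame")
  res
}

#' Write a cluster summary as CSV
#' @param summary a \code{cluster_summary}.
#' @param path output file.
#' @export
write_cluster_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
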