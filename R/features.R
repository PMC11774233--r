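# Frame-wise descriptor tables: apply one descriptor uniformly over an
# ensemble, keyed by (traj, time).

.DESCRIPTORS <- c("r2", "inv_r2", "delta_r2", "re", "zmat", "delta_zmat",
                  "tanh_zmat", "sig_zmat", "soap", "cremer_pople")

#' Build a descriptor table for a whole ensemble
#'
#' Applies the chosen descriptor to every frame and returns a feature table:
#' a data.frame with key columns \code{traj}, \code{time} first and one
#' stable, documented feature column per descriptor component.  Reference-based
#' variants (\code{delta_r2}, \code{re}, \code{delta_zmat}, \code{tanh_zmat},
#' \code{sig_zmat}) require \code{reference}.
#'
#' @param ens an \code{md_ensemble}.
#' @param descriptor one of \code{"r2"}, \code{"inv_r2"}, \code{"delta_r2"},
#'   \code{"re"}, \code{"zmat"}, \code{"delta_zmat"}, \code{"tanh_zmat"},
#'   \code{"sig_zmat"}, \code{"soap"}, \code{"cremer_pople"}.
#' @param reference optional \code{geometry} (e.g. the ground-state minimum)
#'   for reference-based variants.
#' @param connectivity optional Z-matrix connectivity override.
#' @param ring_atoms ordered ring atom indices (for \code{cremer_pople}).
#' @param soap a \code{\link{soap_params}} object (for \code{soap}); defaults
#'   to \code{soap_params(unique(ens$atom_labels))}.
#' @return data.frame feature table; attribute \code{"descriptor"} records
#'   the choice (used by the scaling layer to protect SOAP spectra).
#' @export
descriptor_dataset <- function(ens, descriptor = "r2", reference = NULL,
                               connectivity = NULL, ring_atoms = NULL,
                               soap = NULL) {
  stopifnot(inherits(ens, "md_ensemble"))
  if (!descriptor %in% .DESCRIPTORS)
    stop("unknown descriptor '", descriptor, "'; choose one of: ",
         paste(.DESCRIPTORS, collapse = ", "))
  if (ens$n_frames < 1L) stop("empty ensemble")
  needs_ref <- descriptor %in% c("delta_r2", "re", "delta_zmat",
                                 "tanh_zmat", "sig_zmat")
  if (needs_ref && is.null(reference))
    stop("descriptor '", descriptor, "' needs a reference geometry")

  v_ref <- z_ref <- NULL
  if (!is.null(reference) && descriptor %in% c("delta_r2", "re"))
    v_ref <- pairwise_distance_vector(reference)
  if (!is.null(reference) && grepl("zmat", descriptor))
    z_ref <- zmatrix(reference, connectivity)
  if (descriptor == "soap" && is.null(soap))
    soap <- soap_params(unique(ens$atom_labels))
  if (descriptor == "cremer_pople" && is.null(ring_atoms))
    stop("descriptor 'cremer_pople' needs ring_atoms")

  frame_vec <- function(g) {
    switch(descriptor,
      r2 = pairwise_distance_vector(g),
      inv_r2 = r2_variant(pairwise_distance_vector(g), variant = "inverse"),
      delta_r2 = r2_variant(pairwise_distance_vector(g), v_ref, "delta"),
      re = r2_variant(pairwise_distance_vector(g), v_ref, "re"),
      zmat = zmatrix_vector(zmatrix(g, connectivity)),
      delta_zmat = delta_zmatrix(zmatrix(g, connectivity), z_ref, "none"),
      tanh_zmat = delta_zmatrix(zmatrix(g, connectivity), z_ref, "tanh"),
      sig_zmat = delta_zmatrix(zmatrix(g, connectivity), z_ref, "sig"),
      soap = soap_power_spectrum(g, soap),
      cremer_pople = cremer_pople(g, ring_atoms)$params)
  }
  first <- frame_vec(ens$geometries[[1]])
  mat <- matrix(NA_real_, ens$n_frames, length(first))
  mat[1, ] <- first
  if (ens$n_frames > 1L)
    for (f in 2:ens$n_frames) mat[f, ] <- frame_vec(ens$geometries[[f]])
  if (any(!is.finite(mat)))
    stop("descriptor produced non-finite values")
  out <- data.frame(traj = ens$index$traj, time = ens$index$time)
  feat <- as.data.frame(mat)
  names(feat) <- names(first)
  out <- cbind(out, feat)
  attr(out, "descriptor") <- descriptor
  out
}

#' Split a feature table into keys and feature matrix
#' @param t feature table (data.frame with \code{traj}, \code{time} first).
#' @return list with \code{keys} (data.frame) and \code{x} (numeric matrix).
#' @export
feature_matrix <- function(t) {
  keys <- t[, c("traj", "time"), drop = FALSE]
  x <- as.matrix(t[, setdiff(names(t), c("traj", "time")), drop = FALSE])
  storage.mode(x) <- "double"
  list(keys = keys, x = x)
}
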