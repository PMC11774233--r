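# Preprocessing of feature tables: scaling, stride resampling, random
# subsampling.  All scalers keep their fitted parameters so they can be
# re-applied to new rows.

#' Z-score (standard) scaling
#'
#' Transforms each feature column to (x - mu) / sigma with the population
#' standard deviation (ddof 0).  Constant columns (sigma = 0) are mapped to
#' zero with a warning.  SOAP spectra are protected: their columns form a
#' coherent spectral series whose relative magnitudes carry the structural
#' information, so scaling a table tagged \code{descriptor = "soap"}
#' requires \code{override = TRUE}.
#'
#' @param t feature table (keys \code{traj}, \code{time} first).
#' @param override set \code{TRUE} to scale a SOAP table anyway.
#' @return list with \code{table} (scaled feature table) and \code{params}
#'   (a \code{scaler_params} object).
#' @export
zscore_scale <- function(t, override = FALSE) {
  .check_soap_guard(t, "zscore", override)
  fm <- feature_matrix(t)
  if (nrow(fm$x) == 0L) stop("empty feature table")
  mu <- colMeans(fm$x)
  sigma <- sqrt(colMeans(sweep(fm$x, 2, mu)^2))  # population sd
  const <- sigma == 0
  if (any(const))
    warning(sum(const), " constant feature column(s) mapped to 0")
  sigma_safe <- ifelse(const, 1, sigma)
  scaled <- sweep(sweep(fm$x, 2, mu), 2, sigma_safe, "/")
  scaled[, const] <- 0
  params <- structure(list(kind = "zscore", center = mu, scale = sigma),
                      class = "scaler_params")
  list(table = .rebuild_table(fm$keys, scaled, t), params = params)
}

#' Min-max scaling
#'
#' Rescales each feature column linearly onto \code{range} (default [0, 1]).
#' Constant columns map to the range midpoint with a warning.
#'
#' @inheritParams zscore_scale
#' @param range length-2 numeric target range.
#' @return list with \code{table} and \code{params}.
#' @export
minmax_scale <- function(t, range = c(0, 1), override = FALSE) {
  .check_soap_guard(t, "minmax", override)
  fm <- feature_matrix(t)
  if (nrow(fm$x) == 0L) stop("empty feature table")
  lo <- apply(fm$x, 2, min)
  hi <- apply(fm$x, 2, max)
  const <- hi == lo
  if (any(const))
    warning(sum(const), " constant feature column(s) mapped to range midpoint")
  span <- ifelse(const, 1, hi - lo)
  scaled <- sweep(sweep(fm$x, 2, lo), 2, span, "/")
  scaled[, const] <- 0.5
  scaled <- scaled * diff(range) + range[1]
  params <- structure(list(kind = "minmax", min = lo, max = hi,
                           range = range),
                      class = "scaler_params")
  list(table = .rebuild_table(fm$keys, scaled, t), params = params)
}

.check_soap_guard <- function(t, kind, override) {
  if (identical(attr(t, "descriptor"), "soap") && !isTRUE(override))
    stop("refusing to ", kind, "-scale a SOAP table: feature-wise scaling ",
         "destroys the spectral structure (pass override = TRUE to force)")
}

.rebuild_table <- function(keys, x, original) {
  out <- cbind(keys, as.data.frame(x))
  names(out) <- names(original)
  attr(out, "descriptor") <- attr(original, "descriptor")
  out
}

#' Re-apply fitted scaler parameters
#'
#' @param t feature table with the same feature columns the scaler was
#'   fitted on.
#' @param params a \code{scaler_params} object.
#' @return scaled feature table.
#' @export
apply_scaler <- function(t, params) {
  stopifnot(inherits(params, "scaler_params"))
  fm <- feature_matrix(t)
  x <- fm$x
  if (params$kind == "zscore") {
    sigma_safe <- ifelse(params$scale == 0, 1, params$scale)
    x <- sweep(sweep(x, 2, params$center), 2, sigma_safe, "/")
    x[, params$scale == 0] <- 0
  } else if (params$kind == "minmax") {
    const <- params$max == params$min
    span <- ifelse(const, 1, params$max - params$min)
    x <- sweep(sweep(x, 2, params$min), 2, span, "/")
    x[, const] <- 0.5
    x <- x * diff(params$range) + params$range[1]
  } else stop("unknown scaler kind: ", params$kind)
  .rebuild_table(fm$keys, x, t)
}

#' Invert a z-score scaling
#' @inheritParams apply_scaler
#' @return feature table on the original scale (constant columns restored to
#'   their fitted mean).
#' @export
invert_scaler <- function(t, params) {
  stopifnot(inherits(params, "scaler_params"))
  fm <- feature_matrix(t)
  x <- fm$x
  if (params$kind == "zscore") {
    x <- sweep(sweep(x, 2, params$scale, "*"), 2, params$center, "+")
  } else if (params$kind == "minmax") {
    x <- (x - params$range[1]) / diff(params$range)
    x <- sweep(sweep(x, 2, params$max - params$min, "*"), 2, params$min, "+")
  } else stop("unknown scaler kind: ", params$kind)
  .rebuild_table(fm$keys, x, t)
}

#' Resample a feature table at a coarser time stride
#'
#' Keeps, per trajectory, the frames whose time stamp is an integer multiple
#' of \code{stride_fs} (within 1e-6 fs).  Used to reduce the temporal
#' correlation between consecutive frames before embedding or clustering,
#' e.g. thinning a 0.1 fs series to 0.5 fs.
#'
#' @param t feature table.
#' @param stride_fs target stride, fs (> 0).
#' @return thinned feature table.  If \code{stride_fs} is smaller than the
#'   native step the table is returned unchanged with a warning.
#' @export
resample_by_stride <- function(t, stride_fs) {
  if (stride_fs <= 0) stop("stride_fs must be > 0")
  native <- min(vapply(split(t$time, t$traj), function(tt) {
    if (length(tt) < 2L) Inf else min(diff(sort(tt)))
  }, numeric(1)))
  if (is.finite(native) && stride_fs < native - 1e-9) {
    warning("stride ", stride_fs, " fs smaller than native step ", native,
            " fs; table returned unchanged")
    return(t)
  }
  ratio <- t$time / stride_fs
  keep <- abs(ratio - round(ratio)) <= 1e-6 / stride_fs
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "descriptor") <- attr(t, "descriptor")
  out
}

#' Random subsample of table rows
#'
#' Uniform sampling without replacement, deterministic for a fixed seed;
#' the original row order is preserved among the kept rows.
#'
#' @param t feature table.
#' @param n number of rows to keep (1 <= n <= nrow).
#' @param seed integer RNG seed.
#' @return subsampled feature table.
#' @export
random_subsample <- function(t, n, seed) {
  if (n < 1L || n > nrow(t))
    stop("n must be between 1 and the row count (", nrow(t), ")")
  set.seed(seed)
  keep <- sort(sample.int(nrow(t), n))
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "descriptor") <- attr(t, "descriptor")
  out
}
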