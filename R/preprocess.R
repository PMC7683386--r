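#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a sphere of radius `sphere_radius`.
#' The first frame has no predecessor and gets FD = 0.
#'
#' @param trace Numeric matrix with `T` rows and 6 columns in the order
#'   tx, ty, tz (mm), rx, ry, rz (radians).
#' @param sphere_radius Radius in mm used to convert rotations to
#'   displacements (default 50, the usual head-size convention).
#' @return Numeric vector of length `T` (mm), first entry 0.
#' @export
framewise_displacement <- function(trace, sphere_radius = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) stop("motion trace must have 6 columns", call. = FALSE)
  if (nrow(trace) < 2) stop("motion trace must have >= 2 rows", call. = FALSE)
  check_finite(trace, "motion trace")
  d <- abs(diff(trace))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    sphere_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Subject-level motion quality control
#'
#' Applies the three exclusion rules of the study design: maximum absolute
#' translation above `max_trans` mm, maximum absolute rotation above
#' `max_rot` degrees, or mean framewise displacement above `max_mean_fd`
#' mm. Rotations in the trace are radians and are converted to degrees for
#' the rotation rule.
#'
#' @inheritParams framewise_displacement
#' @param max_trans Translation limit in mm (default 2).
#' @param max_rot Rotation limit in degrees (default 2).
#' @param max_mean_fd Mean-FD limit in mm (default 0.5).
#' @param id Optional subject identifier carried into the report.
#' @return An object of class `qc_report`: list with `id`,
#'   `max_translation` (mm), `max_rotation` (degrees), `mean_fd` (mm),
#'   `pass` (logical) and `reasons` (character vector, empty iff pass).
#' @export
qc_subject <- function(trace, max_trans = 2, max_rot = 2, max_mean_fd = 0.5,
                       sphere_radius = 50, id = NA_character_) {
  trace <- as.matrix(trace)
  fd <- framewise_displacement(trace, sphere_radius)
  max_translation <- max(abs(trace[, 1:3]))
  max_rotation <- max(abs(trace[, 4:6])) * 180 / pi
  mean_fd <- mean(fd)
  reasons <- character(0)
  if (max_translation > max_trans) reasons <- c(reasons, "translation")
  if (max_rotation > max_rot) reasons <- c(reasons, "rotation")
  if (mean_fd > max_mean_fd) reasons <- c(reasons, "mean_fd")
  structure(
    list(id = id, max_translation = max_translation,
         max_rotation = max_rotation, mean_fd = mean_fd,
         pass = length(reasons) == 0, reasons = reasons),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC %s: max|trans| %.2f mm, max|rot| %.2f deg, mean FD %.3f mm -> %s%s\n",
    if (is.na(x$id)) "report" else x$id,
    x$max_translation, x$max_rotation, x$mean_fd,
    if (x$pass) "PASS" else "FAIL",
    if (x$pass) "" else paste0(" (", paste(x$reasons, collapse = ", "), ")")))
  invisible(x)
}

#' Convert a list of QC reports to a data frame
#'
#' @param reports List of `qc_report` objects.
#' @return Data frame with one row per subject.
#' @export
qc_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(id = r$id, max_translation = r$max_translation,
               max_rotation = r$max_rotation, mean_fd = r$mean_fd,
               pass = r$pass,
               reasons = paste(r$reasons, collapse = ";"),
               stringsAsFactors = FALSE)))
}

#' Discard initial volumes of a 4D acquisition
#'
#' Drops the first `k` timepoints from the image (and, when supplied, the
#' motion trace) to let the signal reach steady state.
#'
#' @param img 4D numeric array.
#' @param trace Optional motion matrix with one row per timepoint.
#' @param k Number of leading volumes to discard (default 2).
#' @return List with `image` and `trace` (possibly `NULL`), both trimmed.
#' @export
discard_initial_volumes <- function(img, trace = NULL, k = 2) {
  d <- dim(img)
  if (length(d) != 4) stop("img must be a 4D array", call. = FALSE)
  k <- as.integer(k)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (k >= d[4]) stop("k must be smaller than the number of timepoints",
                      call. = FALSE)
  if (k == 0) return(list(image = img, trace = trace))
  img <- img[, , , (k + 1):d[4], drop = FALSE]
  if (!is.null(trace)) {
    trace <- as.matrix(trace)
    if (nrow(trace) != d[4])
      stop("trace length does not match image time dimension", call. = FALSE)
    trace <- trace[(k + 1):d[4], , drop = FALSE]
  }
  list(image = img, trace = trace)
}

#' Regress nuisance signals out of time series
#'
#' Ordinary least-squares residualization against an intercept plus the
#' given regressors (typically the 6 rigid-body motion parameters), with
#' the original series mean restored afterwards. Accepts a single series
#' or a `T x N` matrix of series (columns residualized jointly).
#'
#' @param x Numeric vector of length `T`, or a `T x N` matrix.
#' @param regressors `T x q` numeric matrix of nuisance signals.
#' @return Residualized series with the same shape as `x`.
#' @export
nuisance_regress <- function(x, regressors) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  Z <- as.matrix(regressors)
  check_finite(x, "series"); check_finite(Z, "regressors")
  T_ <- nrow(x)
  if (nrow(Z) != T_) stop("regressor rows must match series length",
                          call. = FALSE)
  X <- cbind(`(intercept)` = 1, Z)
  if (T_ <= ncol(X))
    stop("series too short for the number of regressors", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("collinear nuisance regressors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qrX, x)
  out <- sweep(res, 2, colMeans(x), "+")
  if (vec) drop(out) else out
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution with `sigma_mm = fwhm / (2 sqrt(2 log 2))`
#' per axis (converted to voxel units), reflective boundary handling.
#' Applies to a 3D volume or volume-by-volume to a 4D image. `fwhm = 0`
#' returns the input unchanged.
#'
#' @param vol 3D or 4D numeric array.
#' @param fwhm Full width at half maximum in mm; scalar or length 3.
#' @param voxel_size Voxel dimensions in mm; scalar or length 3.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(vol, fwhm, voxel_size = c(1, 1, 1)) {
  if (any(fwhm < 0)) stop("fwhm must be non-negative", call. = FALSE)
  if (all(fwhm == 0)) return(vol)
  d <- dim(vol)
  if (!length(d) %in% c(3, 4)) stop("vol must be 3D or 4D", call. = FALSE)
  fwhm <- rep(as.numeric(fwhm), length.out = 3)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  if (length(d) == 3)
    return(cpp_smooth3d(as.numeric(vol), as.integer(d), sigma_vox))
  out <- vol
  for (t in seq_len(d[4]))
    out[, , , t] <- cpp_smooth3d(as.numeric(vol[, , , t]),
                                 as.integer(d[1:3]), sigma_vox)
  out
}
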