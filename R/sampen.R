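#' Template-pair match counts for Sample Entropy
#'
#' Counts matching template pairs of a univariate series at window lengths
#' `m` and `m + 1`. Templates are the length-`m` windows starting at
#' positions `1 .. T - m`; the same starting positions are used at both
#' lengths (Richman-Moorman convention), so every length-(m+1) matching pair
#' is also a length-m matching pair and `A <= B` always holds. Two templates
#' match when their Chebyshev distance (maximum absolute coordinate
#' difference) is at most `r_abs`.
#'
#' @param x Numeric vector, the time series. Must be finite and of length
#'   at least `m + 2`.
#' @param m Integer template length (timepoints), `m >= 1`.
#' @param r_abs Positive absolute tolerance, in the units of `x`.
#' @param strict Logical; if `TRUE` a match requires distance strictly
#'   below `r_abs` (sensitivity variant). Default counts ties as matches.
#' @return A list with components `B` (matching pairs at length `m`) and
#'   `A` (matching pairs at length `m + 1`), both counts of unordered
#'   distinct pairs.
#' @examples
#' match_counts(rep(1, 5), m = 1, r_abs = 0.5)   # B = A = choose(4, 2)
#' @export
match_counts <- function(x, m, r_abs, strict = FALSE) {
  x <- as.numeric(x)
  check_finite(x, "series")
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (length(x) < m + 2)
    stop("series too short: need length >= m + 2", call. = FALSE)
  if (!is.finite(r_abs) || r_abs <= 0)
    stop("r_abs must be positive", call. = FALSE)
  cpp_match_counts(x, m, r_abs, isTRUE(strict))
}

#' Sample Entropy of a time series
#'
#' Sample Entropy (SampEn) is the negative natural logarithm of the
#' conditional probability that two length-`m` windows of the series that
#' match within tolerance still match when extended to length `m + 1`;
#' equivalently `log(B / A)` with the counts of [match_counts()]. Higher
#' values mean more temporal irregularity. With `tolerance_mode = "sd"`
#' (the convention of resting-state brain entropy mapping) the effective
#' tolerance is `r` times the sample standard deviation (n-1
#' normalization, as in MATLAB's `std`) of the full series, which makes
#' the result invariant to affine rescaling of the signal.
#'
#' @inheritParams match_counts
#' @param r Positive tolerance: a dimensionless factor multiplying the
#'   series SD when `tolerance_mode = "sd"`, or an absolute tolerance in
#'   signal units when `tolerance_mode = "absolute"`.
#' @param tolerance_mode `"sd"` (default) or `"absolute"`.
#' @return A single non-negative number, or `NA` when the value is
#'   undefined (`B = 0`, `A = 0`, or zero series SD in `"sd"` mode).
#' @examples
#' sample_entropy(rep(c(1, 2), 5), m = 1, r = 0.5,
#'                tolerance_mode = "absolute")  # 0: every match extends
#' @export
sample_entropy <- function(x, m = 3, r = 0.6,
                           tolerance_mode = c("sd", "absolute"),
                           strict = FALSE) {
  tolerance_mode <- match.arg(tolerance_mode)
  x <- as.numeric(x)
  check_finite(x, "series")
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (length(x) < m + 2)
    stop("series too short: need length >= m + 2", call. = FALSE)
  if (!is.finite(r) || r <= 0) stop("r must be positive", call. = FALSE)
  cpp_sample_entropy(x, m, r, tolerance_mode == "sd", isTRUE(strict))
}

#' Voxelwise brain entropy (BEN) map
#'
#' Applies [sample_entropy()] to every voxel time series of a 4D image
#' inside a brain mask, producing a 3D brain-entropy volume. Voxels where
#' Sample Entropy is undefined (no template matches, or constant signal in
#' SD-relative mode) are set to `NA` and removed from the output mask
#' rather than imputed.
#'
#' @param img 4D numeric array (x, y, z, time), e.g. from [read_image()].
#' @param mask 3D logical array matching the spatial dimensions, or `NULL`
#'   for all voxels.
#' @inheritParams sample_entropy
#' @param voxel_size Numeric length-3 voxel dimensions in mm (metadata,
#'   carried through to outputs).
#' @return An object of class `ben_volume`: a list with `values` (3D array,
#'   `NA` outside the defined mask), `mask` (3D logical array of defined
#'   voxels), `voxel_size`, and the entropy parameters used.
#' @export
ben_map <- function(img, mask = NULL, m = 3, r = 0.6,
                    tolerance_mode = c("sd", "absolute"), strict = FALSE,
                    voxel_size = c(1, 1, 1)) {
  tolerance_mode <- match.arg(tolerance_mode)
  d <- dim(img)
  if (length(d) != 4) stop("img must be a 4D array", call. = FALSE)
  if (d[4] < m + 2)
    stop("image time dimension must be >= m + 2", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(as.integer(dim(mask)), as.integer(d[1:3])))
    stop("mask shape does not match image spatial dimensions", call. = FALSE)
  check_finite(img[rep(as.logical(mask), d[4])], "masked image values")
  vals <- cpp_ben_map(as.numeric(img), as.integer(d),
                      as.logical(mask), as.integer(m), r,
                      tolerance_mode == "sd", isTRUE(strict))
  structure(
    list(values = vals,
         mask = array(as.logical(mask) & is.finite(vals), d[1:3]),
         voxel_size = as.numeric(voxel_size),
         m = as.integer(m), r = r, tolerance_mode = tolerance_mode),
    class = "ben_volume")
}

#' @export
print.ben_volume <- function(x, ...) {
  cat("Brain entropy volume\n")
  cat("  grid: ", paste(dim(x$values), collapse = " x "),
      "  voxel size (mm): ", paste(x$voxel_size, collapse = " x "), "\n",
      sep = "")
  cat("  defined voxels: ", sum(x$mask), "\n", sep = "")
  cat(sprintf("  SampEn(m = %d, r = %g, %s-tolerance); mean %.3f\n",
              x$m, x$r, x$tolerance_mode,
              mean(x$values[x$mask])))
  invisible(x)
}
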