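#' Read a NIfTI-1 image
#'
#' Thin wrapper over [RNifti::readNifti()] that optionally enforces the
#' expected dimensionality. Plain and gzipped files are both accepted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param expect_dims Required number of dimensions (e.g. 4 for a
#'   functional image), or `NULL` for no check.
#' @return An `niftiImage` array; voxel sizes are available via
#'   [RNifti::pixdim()].
#' @export
read_image <- function(path, expect_dims = NULL) {
  img <- RNifti::readNifti(path)
  if (!is.null(expect_dims) && length(dim(img)) != expect_dims)
    stop(sprintf("%s: expected a %dD image, got %dD", path, expect_dims,
                 length(dim(img))), call. = FALSE)
  img
}

#' Write a NIfTI-1 image
#'
#' Writes 32-bit float NIfTI-1; undefined voxels should be `NaN`/`NA` in
#' the array and are stored as NaN.
#'
#' @param data 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel dimensions in mm.
#' @return `path`, invisibly.
#' @export
write_image <- function(data, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(rep(as.numeric(voxel_size), length.out = 3),
                           rep(1, max(0, nd - 3)))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a CSV with the documented schema: mandatory columns `id`,
#' `diagnosis` (HC/SMC/EMCI/LMCI/AD), `age`, `sex` (M/F), `education`;
#' optional `mmse`, `ravlt`, `faq`, `delayed_recall`, `abeta`, `ttau`,
#' `qc_pass`. Unknown diagnosis labels and duplicate ids are rejected;
#' missing values are kept as `NA` (flagged, never silently dropped).
#'
#' @param path CSV path.
#' @return Validated cohort data frame with `diagnosis` as a factor.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("id", "diagnosis", "age", "sex", "education")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols) > 0)
    stop("cohort file lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("duplicate subject ids in cohort file", call. = FALSE)
  bad <- setdiff(unique(tab$diagnosis), stage_levels())
  if (length(bad) > 0)
    stop("unknown diagnosis labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(tab$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  if (any(is.finite(tab$age) & tab$age <= 0))
    stop("ages must be positive", call. = FALSE)
  tab$diagnosis <- factor(tab$diagnosis, levels = stage_levels())
  tab
}

#' Write a cohort table
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a motion-parameter trace
#'
#' Whitespace-delimited text, one row per timepoint, six columns in the
#' order tx ty tz (mm) rx ry rz (radians).
#'
#' @param path File path.
#' @return `T x 6` numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion file must have 6 columns", call. = FALSE)
  check_finite(m, "motion trace")
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Write a motion-parameter trace
#' @param trace `T x 6` numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(trace, path) {
  utils::write.table(format(trace, digits = 10), path,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Build the run manifest recorded with every pipeline run: tool version,
# the full parameter set (every analysis parameter of the method -- m, r,
# voxel_p, cluster k, FD limit, smoothing fwhm -- is always present),
# seeds, timestamps and input checksums.
build_manifest <- function(config, seeds, inputs = character(0),
                           command = "run_pipeline") {
  checksums <- if (length(inputs) > 0) as.list(tools::md5sum(inputs))
               else list()
  list(tool = "benmap",
       version = as.character(utils::packageVersion("benmap")),
       command = command,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config,
       seeds = seeds,
       input_checksums = checksums)
}
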