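#' Acquisition geometry for synthetic cohorts
#'
#' Defaults emulate the study acquisition: 140 timepoints at TR = 3 s on a
#' common voxel grid (the synthetic data are generated already aligned, so
#' no registration is simulated).
#'
#' @param shape Integer length-3 grid shape (default 24 x 24 x 24).
#' @param voxel_size Voxel dimensions in mm (default 3 mm isotropic).
#' @param n_timepoints Number of volumes (default 140).
#' @param tr Repetition time in seconds (default 3).
#' @return A `sim_geometry` list.
#' @export
sim_geometry <- function(shape = c(24, 24, 24), voxel_size = c(3, 3, 3),
                         n_timepoints = 140, tr = 3) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("shape must be 3 dimensions of at least 16 voxels", call. = FALSE)
  if (n_timepoints < 20) stop("need at least 20 timepoints", call. = FALSE)
  structure(list(shape = shape,
                 voxel_size = rep(as.numeric(voxel_size), length.out = 3),
                 n_timepoints = as.integer(n_timepoints), tr = tr),
            class = "sim_geometry")
}

#' Stationary Gaussian AR(1) series
#'
#' The generator's entropy control knob: higher lag-one autocorrelation
#' `phi` gives a smoother, more predictable series and therefore lower
#' Sample Entropy. The first value is drawn from the stationary
#' distribution, so the whole series is stationary with variance
#' `sigma^2 / (1 - phi^2)`.
#'
#' @param n Series length.
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param sigma Innovation standard deviation (default 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
ar1_series <- function(n, phi, sigma = 1, seed = NULL) {
  if (abs(phi) >= 1) stop("|phi| must be < 1", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  with_seed(seed, {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
    innov <- stats::rnorm(n - 1, 0, sigma)
    for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
    x
  })
}

#' Per-group demographic and biomarker distributions
#'
#' Default means and SDs for the five diagnosis stages. Age, sex and MMSE
#' follow the study's published cohort characteristics; education,
#' cognition (RAVLT, FAQ, delayed recall) and CSF biomarkers use values
#' typical of ADNI-style elderly cohorts, with CSF A-beta lower and t-tau
#' higher at later stages. All values are configuration, not a claim of
#' matching any real cohort exactly.
#'
#' @return Nested list, one entry per diagnosis group.
#' @export
cohort_config <- function() {
  g <- function(age_mean, age_sd, age_lo, age_hi, p_male, mmse_mean, mmse_sd,
                ravlt_mean, ravlt_sd, faq_mean, faq_sd, dr_mean, dr_sd,
                abeta_mean, abeta_sd, ttau_mean, ttau_sd)
    list(age_mean = age_mean, age_sd = age_sd, age_lo = age_lo,
         age_hi = age_hi, p_male = p_male, mmse_mean = mmse_mean,
         mmse_sd = mmse_sd, edu_mean = 16, edu_sd = 2.6,
         ravlt_mean = ravlt_mean, ravlt_sd = ravlt_sd,
         faq_mean = faq_mean, faq_sd = faq_sd,
         dr_mean = dr_mean, dr_sd = dr_sd,
         abeta_mean = abeta_mean, abeta_sd = abeta_sd,
         ttau_mean = ttau_mean, ttau_sd = ttau_sd)
  list(
    HC   = g(75.30, 6.96, 65, 95, 24 / 52, 27.56, 2.0, 44, 10, 0.5, 1.0,
             7.5, 4.0, 205, 50, 65, 25),
    SMC  = g(72.44, 5.49, 65, 83, 12 / 27, 28.78, 1.48, 42, 10, 1.0, 2.0,
             7.0, 4.0, 195, 50, 70, 28),
    EMCI = g(71.53, 6.93, 56, 89, 22 / 57, 25.93, 2.5, 36, 11, 3.0, 4.0,
             5.0, 3.5, 185, 50, 80, 35),
    LMCI = g(71.89, 8.26, 57, 88, 24 / 38, 26.59, 2.5, 30, 11, 6.0, 5.0,
             2.5, 2.5, 160, 45, 100, 45),
    AD   = g(72.47, 7.06, 56, 87, 16 / 34, 22.21, 4.0, 22, 8, 13.0, 7.0,
             1.0, 1.5, 140, 40, 125, 55))
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate an ADNI-style cohort table
#'
#' Draws a balanced cohort over the five diagnosis stages with
#' demographics, cognition and CSF biomarkers from [cohort_config()].
#' Fully reproducible given the seed.
#'
#' @param n_per_group Subjects per diagnosis group (>= 2).
#' @param seed Optional integer seed.
#' @param config Per-group distribution list, see [cohort_config()].
#' @return Data frame with columns id, diagnosis, age, sex, education,
#'   mmse, ravlt, faq, delayed_recall, abeta, ttau, qc_pass (NA until QC
#'   is run).
#' @export
simulate_cohort <- function(n_per_group = 20, seed = NULL,
                            config = cohort_config()) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  groups <- stage_levels()
  if (!all(groups %in% names(config))) stop("invalid config", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(groups, function(gname) {
      cf <- config[[gname]]
      n <- n_per_group
      data.frame(
        diagnosis = gname,
        age = round(rtrunc_norm(n, cf$age_mean, cf$age_sd, cf$age_lo,
                                cf$age_hi), 1),
        sex = ifelse(stats::rbinom(n, 1, cf$p_male) == 1, "M", "F"),
        education = round(rtrunc_norm(n, cf$edu_mean, cf$edu_sd, 8, 20)),
        mmse = round(rtrunc_norm(n, cf$mmse_mean, cf$mmse_sd, 0, 30)),
        ravlt = round(rtrunc_norm(n, cf$ravlt_mean, cf$ravlt_sd, 0, 75)),
        faq = round(rtrunc_norm(n, cf$faq_mean, cf$faq_sd, 0, 30)),
        delayed_recall = round(rtrunc_norm(n, cf$dr_mean, cf$dr_sd, 0, 15)),
        abeta = round(rtrunc_norm(n, cf$abeta_mean, cf$abeta_sd, 60, 350), 1),
        ttau = round(rtrunc_norm(n, cf$ttau_mean, cf$ttau_sd, 20, 500), 1),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(id = sprintf("S%03d", seq_len(nrow(out))), out)
    out$diagnosis <- factor(out$diagnosis, levels = groups)
    out$qc_pass <- NA
    out
  })
}

#' Rectangular ROI labels on a synthetic brain grid
#'
#' Places four disjoint rectangular regions -- pseudo-DMN, MTL and PFC
#' (the effect regions) plus a NULL control region -- inside a brain mask
#' with a 2-voxel margin. Block spans scale with the grid.
#'
#' @param geometry A [sim_geometry()] object.
#' @return List with `labels` (3D integer array: 0 background, 1 DMN,
#'   2 MTL, 3 PFC, 4 NULL), `roi_names`, and `brain_mask` (3D logical).
#' @export
make_roi_masks <- function(geometry) {
  d <- geometry$shape
  lo <- function(n) (floor(0.18 * n) + 1):floor(0.42 * n)
  hi <- function(n) (floor(0.58 * n) + 1):floor(0.82 * n)
  labels <- array(0L, d)
  labels[lo(d[1]), lo(d[2]), lo(d[3])] <- 1L  # DMN
  labels[hi(d[1]), lo(d[2]), lo(d[3])] <- 2L  # MTL
  labels[lo(d[1]), hi(d[2]), lo(d[3])] <- 3L  # PFC
  labels[hi(d[1]), hi(d[2]), hi(d[3])] <- 4L  # NULL
  brain <- array(FALSE, d)
  brain[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  if (any(labels[!brain] != 0L)) stop("geometry too small", call. = FALSE)
  list(labels = labels, roi_names = c("DMN", "MTL", "PFC", "NULL"),
       brain_mask = brain)
}

#' Ground-truth effect specification for the synthetic cohort
#'
#' Encodes the study's hypotheses as generator ground truth via the AR(1)
#' coefficient phi of each voxel's signal (higher phi, lower entropy).
#' Inside the effect regions (DMN/MTL/PFC) the stage profile of phi is a
#' "U" -- lowest at EMCI, highest at AD -- so entropy follows the
#' inverse-U trajectory: a slight rise from HC through EMCI, then a
#' catastrophic fall in LMCI and AD. Covariate slopes act on phi per year
#' of age and education and per pg/mL of CSF A-beta, with opposite age and
#' pathology effects in controls and patients and an education effect in
#' controls only. The NULL region and the background carry a fixed phi
#' and no covariate effects.
#'
#' @param phi_stage Named per-stage baseline phi inside effect ROIs.
#' @param phi_null Fixed phi for NULL ROI and background.
#' @param age_slope,education_slope,abeta_slope Named slopes (`control`,
#'   `patient`) on phi per unit of the covariate.
#' @param centers Covariate centering values.
#' @param phi_range Clipping range for the resulting phi.
#' @param noise_sd Stationary SD of each voxel signal.
#' @param motion_fail_rate Fraction of subjects drawn with QC-violating
#'   motion.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(phi_stage = c(HC = 0.50, SMC = 0.45, EMCI = 0.40,
                                      LMCI = 0.62, AD = 0.75),
                        phi_null = 0.50,
                        age_slope = c(control = -0.008, patient = 0.008),
                        education_slope = c(control = 0.012, patient = 0),
                        abeta_slope = c(control = 0.0012,
                                        patient = -0.0012),
                        centers = c(age = 73, education = 16, abeta = 180),
                        phi_range = c(0.02, 0.95),
                        noise_sd = 1,
                        motion_fail_rate = 0.05) {
  stopifnot(all(stage_levels() %in% names(phi_stage)),
            all(phi_stage >= 0 & phi_stage < 1))
  structure(list(phi_stage = phi_stage, phi_null = phi_null,
                 age_slope = age_slope, education_slope = education_slope,
                 abeta_slope = abeta_slope, centers = centers,
                 phi_range = phi_range, noise_sd = noise_sd,
                 motion_fail_rate = motion_fail_rate),
            class = "effect_spec")
}

#' Subject-level phi implied by the effect specification
#'
#' @param record One cohort row.
#' @param effects An [effect_spec()].
#' @return The AR(1) coefficient for this subject's effect-ROI voxels.
#' @export
subject_phi <- function(record, effects) {
  grp <- if (as.character(record$diagnosis) == "HC") "control" else "patient"
  phi <- effects$phi_stage[[as.character(record$diagnosis)]] +
    effects$age_slope[[grp]] * (record$age - effects$centers[["age"]]) +
    effects$education_slope[[grp]] *
      (record$education - effects$centers[["education"]])
  if (is.finite(record$abeta))
    phi <- phi + effects$abeta_slope[[grp]] *
      (record$abeta - effects$centers[["abeta"]])
  min(max(phi, effects$phi_range[1]), effects$phi_range[2])
}

#' Simulate a rigid-body motion trace
#'
#' Low-severity traces are slow random walks that pass all QC rules with
#' wide margin. `"fail"` traces violate one randomly chosen rule:
#' a 2.5 mm translation drift, a 2.5 degree rotation drift, or jittery
#' motion pushing mean framewise displacement above 0.5 mm.
#'
#' @param n_timepoints Trace length.
#' @param severity `"low"` or `"fail"`.
#' @param seed Optional seed.
#' @return `n x 6` matrix (tx ty tz in mm, rx ry rz in radians).
#' @export
simulate_motion <- function(n_timepoints, severity = c("low", "fail"),
                            seed = NULL) {
  severity <- match.arg(severity)
  n <- n_timepoints
  with_seed(seed, {
    walk <- function(sd) cumsum(stats::rnorm(n, 0, sd))
    trace <- cbind(walk(0.02), walk(0.02), walk(0.02),
                   walk(2e-4), walk(2e-4), walk(2e-4))
    if (severity == "fail") {
      mode <- sample(c("translation", "rotation", "fd"), 1)
      ramp <- seq(0, 1, length.out = n)
      if (mode == "translation") {
        trace[, 1] <- trace[, 1] + 2.5 * ramp
      } else if (mode == "rotation") {
        trace[, 4] <- trace[, 4] + 2.5 * pi / 180 * ramp
      } else {
        trace[, 1:3] <- trace[, 1:3] +
          matrix(stats::rnorm(3 * n, 0, 0.25), n, 3)
      }
    }
    colnames(trace) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    trace
  })
}

#' Simulate one subject's 4D image and motion trace
#'
#' Every voxel's time series is a stationary Gaussian AR(1) signal whose
#' coefficient is [subject_phi()] inside the effect regions and the fixed
#' null phi elsewhere; innovations are scaled so all voxels share the same
#' stationary variance. The motion trace is drawn from the severity
#' distribution (QC-failing with probability `motion_fail_rate`, unless
#' `motion_class` overrides the draw).
#'
#' @param record One row of a [simulate_cohort()] table.
#' @param geometry A [sim_geometry()].
#' @param effects An [effect_spec()].
#' @param rois Precomputed [make_roi_masks()] output (recomputed when
#'   `NULL`).
#' @param motion_class `NULL` to draw, or `"low"` / `"fail"` to force.
#' @param seed Optional seed.
#' @return List with `image` (4D array), `motion` (matrix), `phi` (3D
#'   array of generating coefficients) and `motion_class`.
#' @export
simulate_subject_image <- function(record, geometry = sim_geometry(),
                                   effects = effect_spec(), rois = NULL,
                                   motion_class = NULL, seed = NULL) {
  if (is.null(rois)) rois <- make_roi_masks(geometry)
  d <- geometry$shape
  T_ <- geometry$n_timepoints
  phi_map <- array(effects$phi_null, d)
  phi_map[rois$labels %in% 1:3] <- subject_phi(record, effects)
  nv <- prod(d)
  phiv <- as.numeric(phi_map)
  with_seed(seed, {
    if (is.null(motion_class))
      motion_class <- if (stats::runif(1) < effects$motion_fail_rate)
        "fail" else "low"
    motion <- simulate_motion(T_, motion_class)
    sd0 <- effects$noise_sd
    innov_sd <- sd0 * sqrt(1 - phiv^2)
    X <- matrix(0, T_, nv)
    X[1, ] <- stats::rnorm(nv, 0, sd0)
    for (t in 2:T_)
      X[t, ] <- phiv * X[t - 1, ] + stats::rnorm(nv, 0, innov_sd)
    img <- array(as.vector(t(X)), dim = c(d, T_))
    list(image = img, motion = motion, phi = phi_map,
         motion_class = motion_class)
  })
}
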