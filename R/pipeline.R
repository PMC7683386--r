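#' Default analysis parameters
#'
#' The full parameter set of the pipeline with the study's defaults:
#' SampEn with `m = 3`, `r = 0.6` (SD-relative); two volumes discarded;
#' QC limits 2 mm translation, 2 degrees rotation, 0.5 mm mean FD;
#' 4 mm FWHM smoothing; voxel p 0.005 with Monte-Carlo cluster-extent
#' correction at alpha 0.05 and 18-connectivity; permutation FWE for the
#' omnibus F; 6-SD t-tau/A-beta ratio outlier rule.
#'
#' @return Named list of parameters; override entries via the `config`
#'   argument of [run_study()] / [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(n_per_group = 20, seed = 1,
       shape = c(24, 24, 24), voxel_size = c(3, 3, 3),
       n_timepoints = 140, tr = 3,
       m = 3, r = 0.6, tolerance_mode = "sd", strict = FALSE,
       discard = 2, fwhm = 4,
       max_trans = 2, max_rot = 2, max_mean_fd = 0.5,
       voxel_p = 0.005, alpha = 0.05, mc_iter = 500, n_perm = 500,
       connectivity = 18, ratio_k = 6)
}

# discard -> QC -> motion nuisance regression -> smoothing -> BEN map
process_subject <- function(img, trace, params, id = NA_character_) {
  dd <- discard_initial_volumes(img, trace, k = params$discard)
  qc <- qc_subject(dd$trace, max_trans = params$max_trans,
                   max_rot = params$max_rot,
                   max_mean_fd = params$max_mean_fd, id = id)
  if (!qc$pass) return(list(qc = qc, ben = NULL))
  d <- dim(dd$image)
  ts <- t(matrix(dd$image, nrow = prod(d[1:3]), ncol = d[4]))
  ts <- nuisance_regress(ts, dd$trace)
  img2 <- array(t(ts), d)
  if (params$fwhm > 0)
    img2 <- gaussian_smooth(img2, params$fwhm, params$voxel_size)
  ben <- ben_map(img2, mask = params$brain_mask, m = params$m, r = params$r,
                 tolerance_mode = params$tolerance_mode,
                 strict = params$strict, voxel_size = params$voxel_size)
  list(qc = qc, ben = ben)
}

fold_volume <- function(v, mask) {
  a <- array(NA_real_, dim(mask))
  a[mask] <- v
  a
}

# per-group regressions of ROI entropy on age/sex/education and on CSF
# A-beta (age, sex, education as nuisance), matching the study's models
roi_regressions <- function(vals, cohort) {
  out <- list()
  na_res <- list(age_t = NA_real_, age_p = NA_real_,
                 education_t = NA_real_, education_p = NA_real_,
                 abeta_t = NA_real_, abeta_p = NA_real_)
  for (grp in c("control", "patient")) {
    sel <- if (grp == "control") cohort$diagnosis == "HC"
           else cohort$diagnosis != "HC"
    if (sum(sel) < 6) {  # too few subjects for the covariate model
      out[[grp]] <- na_res
      next
    }
    df <- data.frame(val = vals[sel], age = cohort$age[sel],
                     sex = cohort$sex[sel],
                     education = cohort$education[sel],
                     abeta = cohort$abeta[sel])
    use_sex <- length(unique(df$sex)) > 1
    pick <- function(ct, row, col)
      if (row %in% rownames(ct)) ct[row, col] else NA_real_
    f1 <- if (use_sex) val ~ age + sex + education else
      val ~ age + education
    ct <- summary(stats::lm(f1, data = df))$coefficients
    res <- list(age_t = pick(ct, "age", "t value"),
                age_p = pick(ct, "age", "Pr(>|t|)"),
                education_t = pick(ct, "education", "t value"),
                education_p = pick(ct, "education", "Pr(>|t|)"))
    dfa <- df[is.finite(df$abeta), , drop = FALSE]
    if (nrow(dfa) > 6) {
      f2 <- if (use_sex) val ~ abeta + age + sex + education else
        val ~ abeta + age + education
      ca <- summary(stats::lm(f2, data = dfa))$coefficients
      res$abeta_t <- pick(ca, "abeta", "t value")
      res$abeta_p <- pick(ca, "abeta", "Pr(>|t|)")
    } else {
      res$abeta_t <- NA_real_
      res$abeta_p <- NA_real_
    }
    out[[grp]] <- res
  }
  out
}

#' Run the full synthetic brain-entropy study
#'
#' Generates an ADNI-style synthetic cohort, processes every subject
#' (volume discard, motion QC, motion nuisance regression, Gaussian
#' smoothing, voxelwise Sample Entropy), and runs the group analyses:
#' five-group omnibus F with max-statistic permutation FWE control, the
#' AD-vs-HC post-hoc t contrast with Monte-Carlo cluster-extent
#' correction, per-region regressions of entropy on age, education and
#' CSF A-beta separately in controls and patients, and the quadratic
#' stage-trajectory fit.
#'
#' @param config Named list overriding entries of [pipeline_defaults()].
#' @param effects Ground-truth [effect_spec()] for the generator.
#' @param verbose Print stage progress.
#' @return An object of class `ben_study`: cohort with QC outcomes, QC
#'   table, entropy maps, statistic maps, cluster table, per-ROI
#'   regression summaries and the `stage_trajectory` fit.
#' @export
run_study <- function(config = list(), effects = effect_spec(),
                      verbose = FALSE) {
  params <- utils::modifyList(pipeline_defaults(), config)
  geometry <- sim_geometry(params$shape, params$voxel_size,
                           params$n_timepoints, params$tr)
  rois <- make_roi_masks(geometry)
  params$brain_mask <- rois$brain_mask
  say <- function(...) if (verbose) message(sprintf(...))

  seeds <- derive_seeds(params$seed, params$n_per_group * 5 + 2)
  cohort <- simulate_cohort(params$n_per_group, seed = seeds[[1]])
  say("cohort: %d subjects", nrow(cohort))

  bens <- vector("list", nrow(cohort))
  qcs <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sub <- simulate_subject_image(cohort[i, ], geometry, effects,
                                  rois = rois, seed = seeds[[i + 1]])
    ps <- process_subject(sub$image, sub$motion, params,
                          id = cohort$id[i])
    qcs[[i]] <- ps$qc
    bens[[i]] <- ps$ben
    say("subject %s: %s", cohort$id[i],
        if (ps$qc$pass) "pass" else paste(ps$qc$reasons, collapse = ","))
  }
  cohort$qc_pass <- vapply(qcs, `[[`, logical(1), "pass")
  retained <- cohort[cohort$qc_pass, , drop = FALSE]
  retained <- ratio_outlier_filter(retained, k = params$ratio_k)
  bens_ret <- bens[match(retained$id, cohort$id)]
  say("retained %d / %d subjects", nrow(retained), nrow(cohort))

  defined <- rois$brain_mask
  for (b in bens_ret) defined <- defined & b$mask
  Y <- vapply(bens_ret, function(b) b$values[defined],
              numeric(sum(defined)))

  X <- build_design(retained, c("diagnosis", "age", "sex", "education"))
  fit <- fit_glm(Y, X)
  diag_cols <- which(X$assign == "diagnosis")
  fmap <- omnibus_f(fit, diag_cols)
  say("omnibus F computed; permutation FWE threshold (%d perms)",
      params$n_perm)
  f_thr <- permutation_fwe_threshold(Y, X, diag_cols,
                                     n_perm = params$n_perm,
                                     alpha = params$alpha,
                                     seed = seeds[[length(seeds) - 1]])
  tmap <- contrast_t(fit, "diagnosisAD")

  say("Monte-Carlo cluster threshold (%d iterations)", params$mc_iter)
  k_sig <- monte_carlo_cluster_threshold(
    defined, fwhm = params$fwhm, voxel_size = params$voxel_size,
    voxel_p = params$voxel_p, alpha = params$alpha,
    n_iter = params$mc_iter, connectivity = params$connectivity,
    seed = seeds[[length(seeds)]])
  t3 <- fold_volume(tmap$stat, defined)
  p3 <- fold_volume(tmap$p, defined)
  corrected <- apply_cluster_correction(t3, p3, voxel_p = params$voxel_p,
                                        k_min = as.integer(k_sig) - 1L,
                                        connectivity = params$connectivity)
  surviving <- which(!is.na(corrected$stat))
  roi_hit <- function(lab) {
    any(rois$labels[surviving] == lab)
  }

  roi_sets <- list(DMN = rois$labels == 1, MTL = rois$labels == 2,
                   PFC = rois$labels == 3, `NULL` = rois$labels == 4,
                   EFFECT = rois$labels %in% 1:3)
  roi_stats <- lapply(roi_sets, function(sel) {
    vals <- roi_values(bens_ret, sel & defined)
    c(list(values = vals), roi_regressions(vals, retained))
  })
  trajectory <- stage_trajectory_fit(roi_stats$EFFECT$values,
                                     retained$diagnosis)

  structure(
    list(params = params[setdiff(names(params), "brain_mask")],
         geometry = geometry, rois = rois, cohort = cohort,
         retained = retained, qc = qc_table(qcs),
         ben = bens_ret, defined_mask = defined, Y = Y,
         design = X, fit = fit,
         fmap = fmap, f_fwe_threshold = as.numeric(f_thr),
         n_f_fwe = sum(fmap$stat >= as.numeric(f_thr), na.rm = TRUE),
         tmap = tmap, cluster_k = as.integer(k_sig),
         corrected = corrected,
         effect_roi_hits = c(DMN = roi_hit(1), MTL = roi_hit(2),
                             PFC = roi_hit(3)),
         null_roi_hit = roi_hit(4),
         roi_stats = roi_stats, trajectory = trajectory),
    class = "ben_study")
}

#' @export
print.ben_study <- function(x, ...) {
  cat("Synthetic brain-entropy study\n")
  cat(sprintf("  %d subjects simulated, %d retained after QC/biomarker filters\n",
              nrow(x$cohort), nrow(x$retained)))
  cat(sprintf("  omnibus F: %d voxels above the permutation FWE threshold (%.2f)\n",
              x$n_f_fwe, x$f_fwe_threshold))
  cat(sprintf("  AD vs HC: %d surviving clusters (voxel p <= %g, size >= %d)\n",
              nrow(x$corrected$clusters), x$params$voxel_p, x$cluster_k))
  if (!is.null(x$effect_roi_hits))
    cat(sprintf("  effect-ROI hits: DMN %s, MTL %s, PFC %s; NULL ROI hit: %s\n",
                x$effect_roi_hits["DMN"], x$effect_roi_hits["MTL"],
                x$effect_roi_hits["PFC"], x$null_roi_hit))
  if (!is.null(x$trajectory))
    cat(sprintf("  stage-trajectory quadratic: %.4f (p = %.3g)\n",
                x$trajectory$coef["quadratic", "estimate"],
                x$trajectory$coef["quadratic", "p"]))
  invisible(x)
}

#' Run the pipeline and write its outputs
#'
#' Runs [run_study()] (or, when `config$inputs` is given, the same
#' processing on images, motion traces and a cohort table read from disk)
#' and writes every artifact to `out_dir`: the cohort and QC tables,
#' per-subject BEN maps (NIfTI-1, float32, undefined voxels as NaN), the
#' F/t statistic maps and the cluster-corrected t map with its cluster
#' table (0-based voxel indices), the stage-trajectory summary, and a
#' JSON run manifest recording the tool version, full configuration,
#' seeds and input checksums. Reruns with the same configuration and
#' seeds reproduce identical outputs.
#'
#' @param config Named list overriding [pipeline_defaults()]; may carry
#'   `inputs = list(cohort = <csv>, image_dir = <dir>, motion_dir = <dir>)`
#'   to analyze on-disk data (`<id>.nii.gz` / `<id>.txt` per subject).
#' @param out_dir Output directory (created if needed).
#' @param effects Generator ground truth (simulation mode only).
#' @param verbose Print stage progress.
#' @return The `ben_study` object, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir, effects = effect_spec(),
                         verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- config$inputs
  config$inputs <- NULL
  if (is.null(inputs)) {
    study <- run_study(config, effects = effects, verbose = verbose)
    input_files <- character(0)
  } else {
    study <- run_disk_study(config, inputs, verbose = verbose)
    input_files <- c(inputs$cohort,
                     list.files(inputs$image_dir, full.names = TRUE),
                     list.files(inputs$motion_dir, full.names = TRUE))
  }
  params <- study$params
  vs <- params$voxel_size

  write_cohort(study$cohort, file.path(out_dir, "cohort.csv"))
  utils::write.csv(study$qc, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  ben_dir <- file.path(out_dir, "ben")
  dir.create(ben_dir, showWarnings = FALSE)
  for (i in seq_along(study$ben))
    write_image(study$ben[[i]]$values,
                file.path(ben_dir, paste0(study$retained$id[i], ".nii.gz")),
                voxel_size = vs)
  write_image(fold_volume(study$fmap$stat, study$defined_mask),
              file.path(out_dir, "fstat.nii.gz"), voxel_size = vs)
  write_image(fold_volume(study$tmap$stat, study$defined_mask),
              file.path(out_dir, "tstat_AD_vs_HC.nii.gz"), voxel_size = vs)
  write_image(study$corrected$stat,
              file.path(out_dir, "tstat_AD_vs_HC_corrected.nii.gz"),
              voxel_size = vs)
  utils::write.csv(study$corrected$clusters,
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(study$trajectory$stage_summary,
                   file.path(out_dir, "trajectory_stages.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(study$trajectory$coef),
                   file.path(out_dir, "trajectory_fit.csv"))
  sidecar <- list(tstat = list(kind = "t", df = study$tmap$df,
                               contrast = "AD - HC",
                               voxel_p = params$voxel_p,
                               cluster_k = study$cluster_k,
                               connectivity = params$connectivity),
                  fstat = list(kind = "F", df = study$fmap$df,
                               fwe_threshold = study$f_fwe_threshold))
  jsonlite::write_json(sidecar, file.path(out_dir, "statmaps.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- build_manifest(
    config = params, seeds = list(seed = params$seed),
    inputs = input_files,
    command = if (is.null(inputs)) "run_pipeline(simulate)"
              else "run_pipeline(inputs)")
  manifest$computed <- list(cluster_k = study$cluster_k,
                            f_fwe_threshold = study$f_fwe_threshold,
                            n_retained = nrow(study$retained))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(study)
}

# Disk-input variant: same per-subject processing and group statistics on
# images/motion/cohort read from files. ROI-level analyses need a label
# volume; when inputs$roi_labels is absent they are skipped.
run_disk_study <- function(config, inputs, verbose = FALSE) {
  params <- utils::modifyList(pipeline_defaults(), config)
  cohort <- read_cohort(inputs$cohort)
  say <- function(...) if (verbose) message(sprintf(...))
  bens <- vector("list", nrow(cohort))
  qcs <- vector("list", nrow(cohort))
  first <- read_image(file.path(inputs$image_dir,
                                paste0(cohort$id[1], ".nii.gz")), 4)
  params$shape <- dim(first)[1:3]
  params$voxel_size <- RNifti::pixdim(first)[1:3]
  params$n_timepoints <- dim(first)[4]
  d3 <- params$shape
  brain <- array(TRUE, d3)
  params$brain_mask <- brain
  for (i in seq_len(nrow(cohort))) {
    img <- if (i == 1) first else
      read_image(file.path(inputs$image_dir,
                           paste0(cohort$id[i], ".nii.gz")), 4)
    trace <- read_motion(file.path(inputs$motion_dir,
                                   paste0(cohort$id[i], ".txt")))
    ps <- process_subject(img, trace, params, id = cohort$id[i])
    qcs[[i]] <- ps$qc
    bens[[i]] <- ps$ben
    say("subject %s: %s", cohort$id[i],
        if (ps$qc$pass) "pass" else paste(ps$qc$reasons, collapse = ","))
  }
  cohort$qc_pass <- vapply(qcs, `[[`, logical(1), "pass")
  retained <- cohort[cohort$qc_pass, , drop = FALSE]
  if (all(c("ttau", "abeta") %in% names(retained)))
    retained <- ratio_outlier_filter(retained, k = params$ratio_k)
  bens_ret <- bens[match(retained$id, cohort$id)]
  defined <- brain
  for (b in bens_ret) defined <- defined & b$mask
  Y <- vapply(bens_ret, function(b) b$values[defined],
              numeric(sum(defined)))
  X <- build_design(retained, c("diagnosis", "age", "sex", "education"))
  fit <- fit_glm(Y, X)
  diag_cols <- which(X$assign == "diagnosis")
  fmap <- omnibus_f(fit, diag_cols)
  f_thr <- permutation_fwe_threshold(Y, X, diag_cols,
                                     n_perm = params$n_perm,
                                     alpha = params$alpha,
                                     seed = params$seed)
  tmap <- contrast_t(fit, "diagnosisAD")
  k_sig <- monte_carlo_cluster_threshold(
    defined, fwhm = params$fwhm, voxel_size = params$voxel_size,
    voxel_p = params$voxel_p, alpha = params$alpha,
    n_iter = params$mc_iter, connectivity = params$connectivity,
    seed = params$seed)
  t3 <- fold_volume(tmap$stat, defined)
  p3 <- fold_volume(tmap$p, defined)
  corrected <- apply_cluster_correction(t3, p3, voxel_p = params$voxel_p,
                                        k_min = as.integer(k_sig) - 1L,
                                        connectivity = params$connectivity)
  trajectory <- tryCatch(
    stage_trajectory_fit(colMeans(Y), retained$diagnosis),
    error = function(e) NULL)
  structure(
    list(params = params[setdiff(names(params), "brain_mask")],
         cohort = cohort, retained = retained, qc = qc_table(qcs),
         ben = bens_ret, defined_mask = defined, Y = Y, design = X,
         fit = fit, fmap = fmap, f_fwe_threshold = as.numeric(f_thr),
         n_f_fwe = sum(fmap$stat >= as.numeric(f_thr), na.rm = TRUE),
         tmap = tmap, cluster_k = as.integer(k_sig),
         corrected = corrected, trajectory = trajectory),
    class = "ben_study")
}
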