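#' Extract per-subject region-of-interest entropy values
#'
#' Means each subject's brain-entropy map over the defined voxels of a
#' region of interest (a single voxel is allowed).
#'
#' @param ben_maps List of [ben_map()] results (or plain 3D arrays).
#' @param roi 3D logical array, or an integer voxel index triplet
#'   (1-based).
#' @return Numeric vector, one value per subject.
#' @export
roi_values <- function(ben_maps, roi) {
  if (is.numeric(roi) && length(roi) == 3) {
    idx <- as.integer(roi)
    get1 <- function(b) {
      v <- if (inherits(b, "ben_volume")) b$values else b
      v[idx[1], idx[2], idx[3]]
    }
  } else {
    roi <- array(as.logical(roi), dim(roi))
    get1 <- function(b) {
      v <- if (inherits(b, "ben_volume")) b$values else b
      vals <- v[roi]
      vals <- vals[is.finite(vals)]
      if (length(vals) == 0)
        stop("ROI has no defined voxels for a subject", call. = FALSE)
      mean(vals)
    }
  }
  vapply(ben_maps, get1, numeric(1))
}

#' Fit the inverse-U stage trajectory of brain entropy
#'
#' Regresses per-subject entropy values on disease stage treated as an
#' ordinal score (HC = 0, SMC = 1, EMCI = 2, LMCI = 3, AD = 4) with linear
#' and quadratic terms. A negative quadratic coefficient with two-sided
#' p < 0.05 is reported as an inverse-U verdict. Raw stage means and
#' standard errors are always reported alongside, and a second quadratic
#' fit to the five stage means is included so the two readings of the
#' trajectory can be compared.
#'
#' @param values Numeric vector of per-subject entropy values.
#' @param stages Stage codes 0-4, or a factor/character vector with the
#'   levels HC, SMC, EMCI, LMCI, AD.
#' @return Object of class `stage_trajectory` with `coef` (a 3 x 4 matrix
#'   of estimate/SE/t/p for intercept, linear, quadratic), `stage_summary`
#'   (n, mean, SE per stage), `means_coef` (quadratic fit to stage means),
#'   and `inverse_u` (logical verdict).
#' @export
stage_trajectory_fit <- function(values, stages) {
  values <- as.numeric(values)
  if (is.numeric(stages)) {
    s <- as.numeric(stages)
    if (!all(s %in% 0:4)) stop("numeric stages must be in 0..4", call. = FALSE)
  } else {
    f <- factor(as.character(stages), levels = stage_levels())
    if (anyNA(f)) stop("unknown stage labels", call. = FALSE)
    s <- as.numeric(f) - 1
  }
  if (length(values) != length(s))
    stop("values and stages lengths differ", call. = FALSE)
  ok <- is.finite(values) & is.finite(s)
  values <- values[ok]; s <- s[ok]
  if (length(unique(s)) < 3)
    stop("need at least 3 distinct stages for a quadratic fit",
         call. = FALSE)
  fit <- stats::lm(values ~ s + I(s^2))
  # exact polynomial inputs are legitimate here; silence the perfect-fit note
  ct <- suppressWarnings(summary(fit))$coefficients
  coefm <- matrix(NA_real_, 3, 4,
                  dimnames = list(c("intercept", "linear", "quadratic"),
                                  c("estimate", "se", "t", "p")))
  coefm[seq_len(nrow(ct)), ] <- ct
  stage_summary <- do.call(rbind, lapply(sort(unique(s)), function(k) {
    v <- values[s == k]
    data.frame(stage = k, label = stage_levels()[k + 1], n = length(v),
               mean = mean(v),
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                    else NA_real_)
  }))
  means_fit <- stats::lm(mean ~ stage + I(stage^2), data = stage_summary)
  structure(
    list(coef = coefm, stage_summary = stage_summary,
         means_coef = stats::coef(means_fit),
         inverse_u = isTRUE(coefm["quadratic", "estimate"] < 0 &&
                            coefm["quadratic", "p"] < 0.05),
         lm = fit, n = length(values)),
    class = "stage_trajectory")
}

#' @export
print.stage_trajectory <- function(x, ...) {
  cat("Stage trajectory (quadratic in ordinal stage HC=0 .. AD=4)\n")
  cat(sprintf("  n = %d subjects over %d stages\n", x$n,
              nrow(x$stage_summary)))
  cat(sprintf("  quadratic coefficient: %.4f (p = %.3g) -> %s\n",
              x$coef["quadratic", "estimate"], x$coef["quadratic", "p"],
              if (x$inverse_u) "inverse-U" else "no inverse-U verdict"))
  invisible(x)
}

#' @export
summary.stage_trajectory <- function(object, ...) {
  print(object)
  cat("\nStage means:\n")
  print(object$stage_summary, row.names = FALSE)
  cat("\nCoefficients (subject-level fit):\n")
  print(round(object$coef, 5))
  cat("\nQuadratic fit to the 5 stage means:\n")
  print(round(object$means_coef, 5))
  invisible(object)
}

#' @export
coef.stage_trajectory <- function(object, ...) {
  stats::setNames(object$coef[, "estimate"],
                  rownames(object$coef))
}

#' @export
predict.stage_trajectory <- function(object, stage = 0:4, ...) {
  stats::predict(object$lm, newdata = data.frame(s = stage))
}

#' @export
residuals.stage_trajectory <- function(object, ...) {
  stats::residuals(object$lm)
}

#' @export
plot.stage_trajectory <- function(x, ...) {
  ss <- x$stage_summary
  grid <- seq(0, 4, length.out = 101)
  fitv <- predict(x, stage = grid)
  ylim <- range(c(ss$mean - 2 * ss$se, ss$mean + 2 * ss$se, fitv),
                na.rm = TRUE)
  graphics::plot(ss$stage, ss$mean, pch = 19, xaxt = "n", ylim = ylim,
                 xlab = "disease stage", ylab = "brain entropy (SampEn)",
                 ...)
  graphics::axis(1, at = 0:4, labels = stage_levels())
  ok <- is.finite(ss$se)
  graphics::arrows(ss$stage[ok], ss$mean[ok] - ss$se[ok], ss$stage[ok],
                   ss$mean[ok] + ss$se[ok], angle = 90, code = 3,
                   length = 0.04)
  graphics::lines(grid, fitv, col = "gray40", lwd = 2)
  invisible(x)
}
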