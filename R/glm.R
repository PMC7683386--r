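#' Exclude CSF biomarker-ratio outliers
#'
#' Computes the t-tau / A-beta-1-42 ratio for subjects with complete CSF
#' biomarkers and removes subjects whose ratio lies more than `k` sample
#' standard deviations from the mean ratio. Subjects with missing
#' biomarkers are retained and flagged in the `biomarkers_missing` column.
#' Note the rule only has teeth at reasonable sample sizes: a lone extreme
#' ratio among n subjects can be at most `(n-1)/sqrt(n)` sample SDs from
#' the mean, so `k = 6` cannot remove anything below n = 38.
#'
#' @param cohort Cohort data frame with numeric `ttau` and `abeta` columns.
#' @param k SD multiplier (default 6).
#' @return The cohort without outliers, with a logical `biomarkers_missing`
#'   column added; excluded ids are in `attr(, "excluded")`.
#' @export
ratio_outlier_filter <- function(cohort, k = 6) {
  if (!all(c("ttau", "abeta") %in% names(cohort)))
    stop("cohort must carry 'ttau' and 'abeta' columns", call. = FALSE)
  complete <- is.finite(cohort$ttau) & is.finite(cohort$abeta) &
    cohort$abeta > 0
  if (!any(complete))
    stop("no subject has complete CSF biomarkers", call. = FALSE)
  ratio <- ifelse(complete, cohort$ttau / cohort$abeta, NA_real_)
  mu <- mean(ratio[complete])
  s <- stats::sd(ratio[complete])
  out <- complete & is.finite(s) & s > 0 & abs(ratio - mu) > k * s
  out[is.na(out)] <- FALSE
  kept <- cohort[!out, , drop = FALSE]
  kept$biomarkers_missing <- !complete[!out]
  attr(kept, "excluded") <- cohort$id[out]
  kept
}

#' Build a mass-univariate design matrix
#'
#' Assembles an intercept plus the requested terms from a cohort table.
#' `diagnosis` expands to indicator columns against the HC reference;
#' `sex` becomes a single male indicator; numeric covariates are
#' mean-centered. An interaction `"a:b"` is the entry-wise product of its
#' component columns (factors as indicators, continuous terms centered),
#' so a diagnosis-by-pathology interaction column is the centered biomarker
#' times the group indicator. The matrix is checked for full column rank.
#'
#' @param cohort Cohort data frame.
#' @param terms Character vector of term names, e.g.
#'   `c("diagnosis", "age", "sex", "education", "diagnosis:abeta")`.
#' @return Object of class `ben_design`: the `n x p` matrix (`$X`) with
#'   named columns, plus `$assign` mapping columns to terms.
#' @export
build_design <- function(cohort, terms = c("diagnosis", "age", "sex",
                                           "education")) {
  n <- nrow(cohort)
  cols <- list(`(intercept)` = rep(1, n))
  assign <- c("(intercept)")
  term_block <- function(tm) {
    if (tm %in% c("diagnosis", "sex") || !is.numeric(cohort[[tm]])) {
      if (is.null(cohort[[tm]])) stop("unknown term: ", tm, call. = FALSE)
      v <- cohort[[tm]]
      if (anyNA(v)) stop("term '", tm, "' has missing values", call. = FALSE)
      if (tm == "diagnosis") {
        lv <- intersect(stage_levels(), unique(as.character(v)))
        if (length(lv) < 2)
          stop("diagnosis term needs at least 2 groups", call. = FALSE)
        mm <- matrix(sapply(lv[-1], function(l) as.numeric(v == l)),
                     nrow = n)
        colnames(mm) <- paste0("diagnosis", lv[-1])
        mm
      } else if (tm == "sex") {
        matrix(as.numeric(v == "M"), ncol = 1,
               dimnames = list(NULL, "sexM"))
      } else {
        v <- factor(v)
        mm <- sapply(levels(v)[-1], function(l) as.numeric(v == l))
        mm <- matrix(mm, nrow = n)
        colnames(mm) <- paste0(tm, levels(v)[-1])
        mm
      }
    } else {
      v <- cohort[[tm]]
      if (anyNA(v)) stop("term '", tm, "' has missing values", call. = FALSE)
      matrix(v - mean(v), ncol = 1, dimnames = list(NULL, tm))
    }
  }
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    block <- term_block(parts[1])
    if (length(parts) > 1) {
      for (p2 in parts[-1]) {
        b2 <- term_block(p2)
        new <- NULL
        nms <- NULL
        for (i in seq_len(ncol(block)))
          for (j in seq_len(ncol(b2))) {
            new <- cbind(new, block[, i] * b2[, j])
            nms <- c(nms, paste0(colnames(block)[i], ":", colnames(b2)[j]))
          }
        colnames(new) <- nms
        block <- new
      }
    }
    cols[[length(cols) + 1]] <- block
    assign <- c(assign, rep(tm, ncol(block)))
  }
  X <- do.call(cbind, lapply(cols, as.matrix))
  colnames(X)[1] <- "(intercept)"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qrX$pivot[seq_len(qrX$rank)])]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, assign = assign, terms = terms),
            class = "ben_design")
}

#' @export
as.matrix.ben_design <- function(x, ...) x$X

design_matrix <- function(X) {
  if (inherits(X, "ben_design")) X$X else as.matrix(X)
}

#' Fit a voxelwise general linear model
#'
#' Ordinary least squares fitted independently at every voxel (row of `Y`)
#' against a shared design matrix.
#'
#' @param Y Numeric matrix, voxels x subjects (a vector is treated as one
#'   voxel).
#' @param X A [build_design()] object or plain `n x p` design matrix.
#' @return Object of class `ben_glm` with per-voxel `coef` (voxels x p),
#'   `sigma2` (residual variance), residual `df = n - p`, `XtXinv`, and
#'   the inputs needed for nested-model tests.
#' @export
fit_glm <- function(Y, X) {
  X <- design_matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  Y <- as.matrix(Y)
  n <- ncol(Y)
  p <- ncol(X)
  if (nrow(X) != n)
    stop("design rows must equal the number of subjects (columns of Y)",
         call. = FALSE)
  if (n <= p) stop("need more subjects than design columns", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  XtXinv <- chol2inv(chol(crossprod(X)))
  coefs <- Y %*% X %*% XtXinv
  resid <- Y - coefs %*% t(X)
  df <- n - p
  sigma2 <- rowSums(resid^2) / df
  structure(list(coef = coefs, sigma2 = sigma2, df = df,
                 XtXinv = XtXinv, X = X, Y = Y,
                 colnames = colnames(X)),
            class = "ben_glm")
}

#' @export
print.ben_glm <- function(x, ...) {
  cat(sprintf("Voxelwise GLM: %d voxels, %d subjects, %d columns, df = %d\n",
              nrow(x$coef), ncol(x$Y), ncol(x$X), x$df))
  invisible(x)
}

new_stat_map <- function(stat, p, kind, df, extra = list()) {
  structure(c(list(stat = stat, p = p, kind = kind, df = df), extra),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- is.finite(x$stat)
  cat(sprintf("%s-map over %d voxels (df %s): range [%.3f, %.3f], %d undefined\n",
              x$kind, length(x$stat), paste(x$df, collapse = ", "),
              suppressWarnings(min(x$stat[ok])),
              suppressWarnings(max(x$stat[ok])), sum(!ok)))
  invisible(x)
}

#' Voxelwise t contrast
#'
#' Computes `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel with
#' two-sided p-values from the t distribution on the fit's residual
#' degrees of freedom. Voxels with zero residual variance are flagged
#' undefined (`NA`).
#'
#' @param fit A [fit_glm()] object.
#' @param contrast Numeric contrast vector of length p, or the name of a
#'   single design column.
#' @return Object of class `stat_map` with `stat`, `p`, `kind = "t"`, `df`.
#' @export
contrast_t <- function(fit, contrast) {
  if (is.character(contrast)) {
    idx <- match(contrast, fit$colnames)
    if (is.na(idx)) stop("unknown design column: ", contrast, call. = FALSE)
    cvec <- rep(0, ncol(fit$X)); cvec[idx] <- 1
  } else cvec <- as.numeric(contrast)
  if (length(cvec) != ncol(fit$X))
    stop("contrast length must equal the number of design columns",
         call. = FALSE)
  num <- drop(fit$coef %*% cvec)
  vc <- drop(t(cvec) %*% fit$XtXinv %*% cvec)
  se <- sqrt(fit$sigma2 * vc)
  tstat <- ifelse(se > 0, num / se, ifelse(num == 0, 0, NA_real_))
  pval <- 2 * stats::pt(-abs(tstat), df = fit$df)
  new_stat_map(tstat, pval, "t", fit$df, list(contrast = cvec))
}

#' Voxelwise omnibus F test
#'
#' Nested-model F statistic for dropping a set of design columns:
#' `F = ((RSS_reduced - RSS_full)/q) / (RSS_full/df_full)`, with p-values
#' from `F(q, df_full)`. Voxels with zero full-model residual are flagged
#' undefined.
#'
#' @param fit A [fit_glm()] object.
#' @param cols Columns under test: integer indices, column names, or a
#'   term name from the design's `assign` map.
#' @return Object of class `stat_map` with `kind = "F"` and `df = c(q, df)`.
#' @export
omnibus_f <- function(fit, cols) {
  cols <- resolve_cols(fit, cols)
  q <- length(cols)
  Xr <- fit$X[, -cols, drop = FALSE]
  rss_full <- fit$sigma2 * fit$df
  qr_r <- qr(Xr)
  rss_red <- colSums(qr.resid(qr_r, t(fit$Y))^2)
  fstat <- ((rss_red - rss_full) / q) / (rss_full / fit$df)
  # zero residual variance (noiseless fit or constant voxel): undefined
  ss_total <- rowSums((fit$Y - rowMeans(fit$Y))^2)
  fstat[rss_full <= 1e-12 * ss_total | ss_total <= 0] <- NA_real_
  fstat <- pmax(fstat, 0)
  pval <- stats::pf(fstat, q, fit$df, lower.tail = FALSE)
  new_stat_map(fstat, pval, "F", c(q, fit$df), list(cols = cols))
}

resolve_cols <- function(fit, cols) {
  if (is.character(cols)) {
    idx <- match(cols, fit$colnames)
    if (anyNA(idx)) {
      # maybe a term name covering several columns
      if (length(cols) == 1 && !is.null(attr(fit$X, "assign_terms"))) {
        idx <- which(attr(fit$X, "assign_terms") == cols)
      } else if (length(cols) == 1) {
        idx <- grep(paste0("^", cols), fit$colnames)
      }
      if (length(idx) == 0 || anyNA(idx))
        stop("unknown design columns: ", paste(cols, collapse = ", "),
             call. = FALSE)
    }
    cols <- idx
  }
  sort(unique(as.integer(cols)))
}

#' Max-statistic permutation threshold for family-wise error control
#'
#' Freedman-Lane permutation of reduced-model residuals: the response is
#' rebuilt as reduced-model fitted values plus permuted reduced-model
#' residuals, the omnibus F for the columns under test is recomputed over
#' all voxels, and the maximum F across voxels is recorded per
#' permutation. The returned threshold is the `(1 - alpha)` empirical
#' quantile of that max-F distribution; comparing each voxel's observed F
#' against it controls the family-wise error rate at `alpha`.
#'
#' @inheritParams omnibus_f
#' @param Y Voxels x subjects response matrix.
#' @param X Design (matrix or [build_design()] object).
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Optional integer seed; the threshold is deterministic
#'   given the seed.
#' @return The F threshold (scalar), with the max-F sample in
#'   `attr(, "max_stats")`.
#' @export
permutation_fwe_threshold <- function(Y, X, cols, n_perm = 1000,
                                      alpha = 0.05, seed = NULL) {
  X <- design_matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  Y <- as.matrix(Y)
  n <- ncol(Y)
  fit <- fit_glm(Y, X)
  cols <- resolve_cols(fit, cols)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (n_perm * alpha < 1)
    stop("too few permutations to resolve the requested alpha",
         call. = FALSE)
  q <- length(cols)
  Xr <- X[, -cols, drop = FALSE]
  qr_r <- qr(Xr)
  qr_f <- qr(X)
  E <- t(qr.resid(qr_r, t(Y)))          # reduced-model residuals
  df_full <- n - ncol(X)
  max_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Ep <- E[, sample.int(n), drop = FALSE]
      rss_f <- colSums(qr.resid(qr_f, t(Ep))^2)
      rss_r <- colSums(qr.resid(qr_r, t(Ep))^2)
      f <- ((rss_r - rss_f) / q) / (rss_f / df_full)
      max(f[is.finite(f)], 0)
    }, numeric(1))
  })
  idx <- max(1L, min(n_perm, ceiling((1 - alpha) * n_perm)))
  thr <- sort(max_stats)[idx]
  attr(thr, "max_stats") <- max_stats
  thr
}
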