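#' Label connected suprathreshold clusters
#'
#' Connected-component decomposition of a 3D boolean lattice under 6-, 18-
#' or 26-neighbor connectivity. The cluster table is ordered
#' lexicographically by peak voxel index so the labeling is deterministic.
#'
#' @param binary 3D logical array.
#' @param connectivity One of 6 (faces), 18 (faces + edges, the common
#'   neuroimaging default) or 26 (faces + edges + corners).
#' @param stat Optional 3D numeric array used to locate each cluster's
#'   peak (defaults to all-ones, so the peak is the first voxel in scan
#'   order).
#' @return List with `labels` (3D integer array, 0 = background) and
#'   `table`, a data frame with one row per cluster: `label`, `size`
#'   (voxels), `peak_stat`, and 0-based peak indices `peak_i/j/k`.
#' @export
label_clusters <- function(binary, connectivity = 18, stat = NULL) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  d <- dim(binary)
  if (length(d) != 3) stop("binary must be a 3D array", call. = FALSE)
  labels <- cpp_label_clusters(as.logical(binary), as.integer(d),
                               as.integer(connectivity))
  nlab <- max(labels)
  if (nlab == 0) {
    tab <- data.frame(label = integer(0), size = integer(0),
                      peak_stat = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0))
    return(list(labels = labels, table = tab))
  }
  if (is.null(stat)) stat <- array(1, d)
  rows <- lapply(seq_len(nlab), function(l) {
    idx <- which(labels == l)
    s <- abs(stat[idx])
    peak_flat <- idx[which.max(s)]
    pk <- arrayInd(peak_flat, d) - 1L
    data.frame(label = l, size = length(idx), peak_stat = stat[peak_flat],
               peak_i = pk[1], peak_j = pk[2], peak_k = pk[3])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$peak_i, tab$peak_j, tab$peak_k), , drop = FALSE]
  rownames(tab) <- NULL
  list(labels = labels, table = tab)
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Estimates the null distribution of the maximum suprathreshold cluster
#' size by simulating independent Gaussian fields on the mask grid,
#' smoothing them to the stated FWHM, re-standardizing within the mask,
#' and thresholding two-sidedly at the voxel-level p. The returned k is
#' the smallest cluster size whose family-wise probability of occurring
#' anywhere by chance is at most `alpha`: clusters of `size >= k` are
#' significant (equivalently, require `size > k - 1`).
#'
#' @param mask 3D logical array defining the analysis grid.
#' @param fwhm Applied smoothing FWHM in mm (the smoothness of the data
#'   entering inference; taken as known, not estimated).
#' @param voxel_size Voxel dimensions in mm.
#' @param voxel_p Voxel-level two-sided p threshold (default 0.005).
#' @param alpha Cluster-level family-wise error level (default 0.05).
#' @param n_iter Number of simulated null fields (default 1000).
#' @param connectivity Cluster connectivity (default 18).
#' @param seed Optional seed; the threshold is deterministic given it.
#' @return Minimum significant cluster size `k` (voxels); the simulated
#'   max-cluster sizes are in `attr(, "max_sizes")`.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm, voxel_size,
                                          voxel_p = 0.005, alpha = 0.05,
                                          n_iter = 1000, connectivity = 18,
                                          seed = NULL) {
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be a 3D array", call. = FALSE)
  if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must be in (0, 1)",
                                         call. = FALSE)
  if (n_iter < 200) stop("n_iter must be >= 200", call. = FALSE)
  nm <- sum(mask)
  if (nm < 8) stop("mask too small for cluster simulation", call. = FALSE)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  max_sizes <- with_seed(seed, {
    vapply(seq_len(n_iter), function(b) {
      z <- array(stats::rnorm(prod(d)), d)
      if (any(fwhm > 0)) z <- gaussian_smooth(z, fwhm, voxel_size)
      v <- z[mask]
      z[mask] <- (v - mean(v)) / stats::sd(v)
      supra <- array(FALSE, d)
      supra[mask] <- abs(z[mask]) >= zthr
      if (!any(supra)) return(0L)
      lab <- cpp_label_clusters(supra, as.integer(d),
                                as.integer(connectivity))
      max(tabulate(lab[lab > 0L]))
    }, integer(1))
  })
  kmax <- max(max_sizes)
  k <- 1L
  while (k <= kmax && mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(k, max_sizes = max_sizes)
}

#' Apply voxel + cluster-extent correction to a statistic map
#'
#' Retains voxels with `p <= voxel_p` that belong to connected clusters of
#' size strictly greater than `k_min`.
#'
#' @param stat 3D numeric statistic array.
#' @param p 3D numeric p-value array of the same shape.
#' @param voxel_p Voxel-level p threshold (default 0.005).
#' @param k_min Minimum cluster extent; only clusters with `size > k_min`
#'   survive. Pass `k - 1` for a [monte_carlo_cluster_threshold()] value
#'   `k`.
#' @param connectivity Cluster connectivity (default 18).
#' @return List with `stat` (array, `NA` outside surviving clusters),
#'   `labels` (surviving-cluster labels) and `clusters` (the cluster
#'   table of survivors).
#' @export
apply_cluster_correction <- function(stat, p, voxel_p = 0.005, k_min,
                                     connectivity = 18) {
  d <- dim(stat)
  if (!identical(d, dim(p))) stop("stat and p shapes differ", call. = FALSE)
  supra <- array(is.finite(p) & p <= voxel_p, d)
  lab <- label_clusters(supra, connectivity, stat = stat)
  keep <- lab$table$size > k_min
  tab <- lab$table[keep, , drop = FALSE]
  rownames(tab) <- NULL
  out <- array(NA_real_, d)
  if (nrow(tab) > 0) {
    keep_vox <- lab$labels %in% tab$label
    out[keep_vox] <- stat[keep_vox]
  }
  labels <- lab$labels
  labels[!(labels %in% tab$label)] <- 0L
  list(stat = out, labels = labels, clusters = tab)
}
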