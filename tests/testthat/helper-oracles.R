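# Independent brute-force Sample Entropy oracle: plain double loop over
# template pairs, O(T^2 m), sharing no code with the compiled path.
sampen_oracle <- function(x, m, r_abs) {
  T <- length(x)
  N <- T - m
  B <- 0
  A <- 0
  for (i in 1:(N - 1)) {
    js <- (i + 1):N
    dm <- rep(0, length(js))
    for (k in 0:(m - 1)) dm <- pmax(dm, abs(x[i + k] - x[js + k]))
    dm1 <- pmax(dm, abs(x[i + m] - x[js + m]))
    B <- B + sum(dm <= r_abs)
    A <- A + sum(dm1 <= r_abs)
  }
  list(B = B, A = A,
       H = if (A > 0 && B > 0) log(B / A) else NA_real_)
}

# Independent connected-components oracle: igraph over the adjacency graph
# of suprathreshold voxels.
cluster_sizes_oracle <- function(binary, connectivity) {
  idx <- which(binary)
  n <- length(idx)
  if (n == 0) return(integer(0))
  co <- arrayInd(idx, dim(binary))
  edges <- NULL
  for (i in seq_len(n)) {
    if (i == n) break
    d <- abs(sweep(co[(i + 1):n, , drop = FALSE], 2, co[i, ]))
    mx <- apply(d, 1, max)
    s <- rowSums(d)
    adj <- switch(as.character(connectivity),
                  "6"  = s == 1,
                  "18" = mx == 1 & s <= 2,
                  "26" = mx == 1)
    js <- which(adj) + i
    if (length(js) > 0) edges <- rbind(edges, cbind(i, js))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}

# small deterministic cohort for design/GLM toys
toy_cohort <- function(n_per_group = 3, groups = c("HC", "AD")) {
  n <- n_per_group * length(groups)
  data.frame(id = sprintf("T%02d", 1:n),
             diagnosis = factor(rep(groups, each = n_per_group),
                                levels = c("HC", "SMC", "EMCI", "LMCI",
                                           "AD")),
             age = seq(65, 85, length.out = n),
             sex = rep(c("M", "F"), length.out = n),
             education = rep(c(12, 16, 20), length.out = n),
             abeta = seq(120, 240, length.out = n),
             ttau = seq(60, 130, length.out = n),
             stringsAsFactors = FALSE)
}
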