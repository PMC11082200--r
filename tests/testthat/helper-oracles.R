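# Independent oracles, deliberately written from first principles rather
# than via the package's own code paths.

# Pearson correlation by the explicit sum formula
oracle_pearson <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Fisher z through the logarithm form
oracle_fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

# Literal Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k q / m, reject those; adjusted values by the defining minimum.
oracle_bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(ord == i)          # rank of p[i]
    cand <- Inf
    for (j in k:m) {
      cand <- min(cand, m * p[ord[j]] / j)
    }
    adj[i] <- min(1, cand)
  }
  adj
}

# Brute-force ROI retention: count voxels one by one
oracle_roi_retention <- function(atlas, mask, min_voxels, min_overlap) {
  a <- as.vector(atlas); m <- as.vector(mask)
  labs <- sort(unique(a[a > 0]))
  keep <- logical(length(labs))
  for (i in seq_along(labs)) {
    n <- 0; inm <- 0
    for (v in seq_along(a)) {
      if (a[v] == labs[i]) {
        n <- n + 1
        if (m[v] != 0) inm <- inm + 1
      }
    }
    keep[i] <- (n >= min_voxels) && (inm / n >= min_overlap)
  }
  names(keep) <- labs
  keep
}
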