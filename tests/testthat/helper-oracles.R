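# Independent brute-force oracles used to cross-check the implementation.

# Kendall tau-b by explicit O(n^2) pair counting with tie correction
bf_kendall <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0; ta <- 0; tb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- sign(a[j] - a[i]); db <- sign(b[j] - b[i])
    if (da == 0 && db == 0) next
    if (da == 0) { ta <- ta + 1; next }
    if (db == 0) { tb <- tb + 1; next }
    if (da == db) C <- C + 1 else D <- D + 1
  }
  (C - D) / sqrt((C + D + ta) * (C + D + tb))
}

# AUC by exhaustive used x available comparison, ties counted half
bf_auc <- function(scores, case) {
  s1 <- scores[case == 1]; s0 <- scores[case == 0]
  tot <- 0
  for (u in s1) tot <- tot + sum(u > s0) + 0.5 * sum(u == s0)
  tot / (length(s1) * length(s0))
}

# weighted kappa straight from the confusion-matrix formula
bf_weighted_kappa <- function(bA, bB, n_bins) {
  o <- matrix(0, n_bins, n_bins)
  for (k in seq_along(bA)) o[bA[k], bB[k]] <- o[bA[k], bB[k]] + 1
  o <- o / length(bA)
  e <- rowSums(o) %o% colSums(o)
  v <- abs(row(o) - col(o)) / (n_bins - 1)
  1 - sum(v * o) / sum(v * e)
}

# 8-connected component labelling of a 0/1 matrix (flood fill)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (mask[r0, c0] != 1 || lab[r0, c0] != 0L) next
    comp <- comp + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- comp
    while (length(queue)) {
      rc <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- rc[1] + dr; c <- rc[2] + dc
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] == 1 && lab[r, c] == 0L) {
          lab[r, c] <- comp
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  comp
}

# small raster template helpers
template_raster <- function(nr = 40, nc = 40, cell = 1, x0 = 0, y0 = 0) {
  grid_raster(matrix(0, nr, nc), x0, y0, cell)
}

# a compact landscape bundle for pipeline-level tests
tiny_fixture <- function(seed = 5, nr = 40, nc = 40) {
  dem <- generate_dem(nr, nc, 100, seed = derive_seed(seed, "dem"))
  canopy <- generate_canopy(dem, seed = derive_seed(seed, "canopy"))
  valley <- grid_raster((dem$values < 1500) * 1, cell_size = 100)
  sites <- place_feeding_sites(8, valley, 300, seed = seed)
  dist_fs <- path_distance_3d(dem, sites)
  list(dem = dem, canopy = canopy, valley = valley, sites = sites,
       dist_fs = dist_fs, prox = proximity_raster(dist_fs, 50))
}
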