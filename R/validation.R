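#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall rank correlation, computed with Knight's
#' sort-and-count algorithm (mergesort inversion counting), with a
#' two-sided p-value from the tie-corrected normal approximation, or from
#' exact permutation enumeration for `n <= 8`.
#'
#' @param a,b numeric vectors of equal length `>= 2`.
#' @return list with `tau` and `p`.
#' @export
kendall_tau <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("vectors must have equal length")
  if (n < 2L) stop("need at least two observations")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop("no variation: a vector is entirely tied")

  tau <- kendall_tau_stat(a, b)

  if (n <= 8L) {
    perms <- permutations_of(n)
    tobs <- abs(tau)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(kendall_tau_stat(a, b[perms[i, ]])) >= tobs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else {
    # tie-corrected variance of S (Kendall 1970)
    S <- kendall_S(a, b)
    t_a <- table(a); t_b <- table(b)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(t_a * (t_a - 1) * (2 * t_a + 5))
    vu <- sum(t_b * (t_b - 1) * (2 * t_b + 5))
    v1 <- sum(t_a * (t_a - 1)) * sum(t_b * (t_b - 1)) / (2 * n * (n - 1))
    v2 <- sum(t_a * (t_a - 1) * (t_a - 2)) * sum(t_b * (t_b - 1) * (t_b - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- if (varS > 0) S / sqrt(varS) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, p = p)
}

# S = concordant - discordant via mergesort inversion counting; sorting by
# (a, b) makes strict inversions of b exactly the discordant pair count
# (tied-a blocks are internally b-sorted and contribute none)
kendall_S <- function(a, b) {
  n <- length(a)
  ord <- order(a, b)
  b <- b[ord]
  n0 <- n * (n - 1) / 2
  t_a <- table(a); t_b <- table(b)
  n1 <- sum(t_a * (t_a - 1) / 2)
  n2 <- sum(t_b * (t_b - 1) / 2)
  joint <- table(paste(a[ord], b, sep = "\r"))
  n3 <- sum(joint * (joint - 1) / 2)
  D <- count_inversions(b)
  (n0 - n1 - n2 + n3) - 2 * D
}

kendall_tau_stat <- function(a, b) {
  n <- length(a)
  n0 <- n * (n - 1) / 2
  t_a <- table(a); t_b <- table(b)
  n1 <- sum(t_a * (t_a - 1) / 2)
  n2 <- sum(t_b * (t_b - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) stop("no variation: a vector is entirely tied")
  kendall_S(a, b) / denom
}

# strict inversions (pairs i < j with x[i] > x[j]) by divide and conquer;
# cross-half pairs counted with findInterval on the sorted halves
count_inversions <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  mid <- n %/% 2L
  left <- x[1:mid]; right <- x[(mid + 1L):n]
  inv <- count_inversions(left) + count_inversions(right)
  left <- sort(left); right <- sort(right)
  # for each l in left, the number of r in right strictly below l
  inv + sum(findInterval(left, right, left.open = TRUE))
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' ROC area under the curve of a fitted RSF
#'
#' Rank-based AUC: the probability that a randomly chosen used row scores
#' higher than a randomly chosen available row under the model's linear
#' predictor, ties counted half.
#'
#' @param model an `rsf_model`.
#' @param design a `uaa_design` with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(model, design) {
  scores <- rsf_scores(model, design)
  auc_from_scores(scores, design$case)
}

rsf_scores <- function(model, design) {
  b <- model$beta
  b[["cc"]] * design$cc + b[["sd"]] * design$sd +
    b[["prox"]] * design$prox + b[["inter"]] * design$inter
}

auc_from_scores <- function(scores, case) {
  n1 <- sum(case == 1); n0 <- sum(case == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties counted half
  (sum(r[case == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# per-bin used counts and cell counts for one Rp surface; bins are n_bins
# quantile classes (by cell count) of the surface being validated
aa_bin_counts <- function(rp, used, n_bins = 10) {
  vals <- as.vector(rp$raster$values)
  fin <- is.finite(vals)
  edges <- stats::quantile(vals[fin], probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE)
  edges[1] <- -Inf; edges[n_bins + 1] <- Inf
  if (any(diff(edges[2:n_bins]) <= 0))
    stop("quantile degenerate: a prediction bin has zero area")
  cell_bin <- findInterval(vals[fin], edges, left.open = TRUE,
                           rightmost.closed = TRUE) # right-closed intervals
  pt_vals <- extract_at(rp$raster, used$x, used$y)
  pt_bin <- findInterval(pt_vals, edges, left.open = TRUE, rightmost.closed = TRUE)
  list(used = tabulate(pt_bin, n_bins), cells = tabulate(cell_bin, n_bins))
}

#' Area-adjusted use-frequency validation of one Rp surface
#'
#' Bins the surface into `n_bins` quantile classes by cell count, computes
#' per-bin area-adjusted frequencies of observed use
#' (`(used in bin / total used) / (cells in bin / total cells)`) and
#' returns the Kendall rank correlation between bin rank and adjusted
#' frequency. A well-calibrated habitat model yields a monotone increase.
#'
#' @param rp an `rp_map`.
#' @param used_points data.frame of used fixes with `x`, `y` inside the map.
#' @param n_bins number of quantile bins (default 10).
#' @return list with `tau`, `p`, and `adjusted_freq` (length `n_bins`).
#' @export
area_adjusted_tau <- function(rp, used_points, n_bins = 10) {
  validate_map_use(list(rp), used_points, n_bins)
}

#' Area-adjusted validation across several monthly Rp surfaces
#'
#' The multi-surface generalisation used by cross-validation and temporal
#' validation: each surface is binned into its own `n_bins` equal-area
#' quantile classes, each used point is binned on the surface of its own
#' winter-month, and used/cell counts are pooled by bin rank before the
#' area adjustment. With one surface this is exactly [area_adjusted_tau()].
#'
#' @param rp_maps list of `rp_map` objects; when named by
#'   `"<winter>_<month>"` keys, used points are routed by
#'   `paste(winter, month, sep = "_")`, otherwise all points are scored on
#'   every map's own key match or the single map provided.
#' @param used data.frame of used fixes (`x`, `y`, and `winter`/`month`
#'   when several maps are given).
#' @param n_bins number of quantile bins.
#' @return list with `tau`, `p`, `adjusted_freq`.
#' @export
validate_map_use <- function(rp_maps, used, n_bins = 10) {
  if (length(rp_maps) == 0L) stop("no Rp surfaces given")
  used_counts <- numeric(n_bins); cell_counts <- numeric(n_bins)
  if (length(rp_maps) == 1L) {
    bc <- aa_bin_counts(rp_maps[[1]], used, n_bins)
    used_counts <- bc$used; cell_counts <- bc$cells
  } else {
    key <- paste(used$winter, used$month, sep = "_")
    missing <- setdiff(unique(key), names(rp_maps))
    if (length(missing))
      stop(sprintf("no Rp surface for: %s", paste(missing, collapse = ", ")))
    for (k in intersect(names(rp_maps), unique(key))) {
      bc <- aa_bin_counts(rp_maps[[k]], used[key == k, , drop = FALSE], n_bins)
      used_counts <- used_counts + bc$used
      cell_counts <- cell_counts + bc$cells
    }
  }
  if (sum(used_counts) == 0) stop("no used points fall on the surfaces")
  adj <- (used_counts / sum(used_counts)) / (cell_counts / sum(cell_counts))
  kt <- kendall_tau(seq_len(n_bins), adj)
  list(tau = kt$tau, p = kt$p, adjusted_freq = adj)
}

#' Restrict an Rp surface to a validated extent
#'
#' Sets cells outside a home-range polygon to missing so that quantile
#' bins, cell counts and area-adjusted frequencies are computed over the
#' region the model actually contrasts use against (the availability
#' polygon), not over uninhabitable parts of the landscape.
#'
#' @param rp an `rp_map`.
#' @param polygon a `home_range` aligned with the map.
#' @return the masked `rp_map`.
#' @export
mask_surface <- function(rp, polygon) {
  stopifnot_aligned(rp$raster, polygon$mask)
  rp$raster$values[polygon$mask$values != 1] <- NA_real_
  rp
}

#' k-fold cross-validation of the RSF
#'
#' Partitions the design into `k` folds stratified by case (so every
#' training set keeps the 1:1 used:available structure), refits the RSF on
#' the other `k - 1` folds, predicts each held-out used point's quantile
#' bin on the refitted Rp surface of its own winter-month, and scores the
#' fold with the area-adjusted Kendall tau. Folds with fewer than 10
#' held-out used points are rejected as uninformative.
#'
#' @param design a `uaa_design`.
#' @param snow_by_key named list of monthly snow rasters
#'   (`"<winter>_<month>"`).
#' @param canopy,dist_fs aligned covariate rasters.
#' @param dist_floor_m proximity floor (m).
#' @param k number of folds (default 5).
#' @param n_bins quantile bins (default 10).
#' @param seed integer RNG seed.
#' @param mode `"spatial"` or `"temporal"` label carried on the report.
#' @param extent optional `home_range`; when given, each fold's Rp
#'   surface is restricted to it ([mask_surface()]) and held-out used
#'   points outside it are dropped before scoring.
#' @return a `validation_report`: `per_fold_tau`, `per_fold_p`,
#'   `mean_tau`, `n_bins`, `k_folds`, `mode`.
#' @export
kfold_validate <- function(design, snow_by_key, canopy, dist_fs,
                           dist_floor_m = canopy$cell_size / 2,
                           k = 5, n_bins = 10, seed = 1, mode = "spatial",
                           extent = NULL) {
  if (k < 2) stop("k must be >= 2")
  set.seed(derive_seed(seed, "kfold"))
  fold <- integer(nrow(design))
  for (cls in c(0, 1)) {
    idx <- which(design$case == cls)
    if (length(idx) < k) stop("a case class has fewer rows than folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  taus <- numeric(k); ps <- numeric(k)
  for (f in seq_len(k)) {
    train <- design[fold != f, , drop = FALSE]
    test_used <- design[fold == f & design$case == 1, , drop = FALSE]
    if (length(unique(train$case)) < 2L) stop("a training fold has a single class")
    if (!is.null(extent))
      test_used <- test_used[in_home_range(extent, test_used$x, test_used$y), ,
                             drop = FALSE]
    if (nrow(test_used) < 10L)
      stop("fewer than 10 held-out used points in a fold")
    m <- fit_rsf(train)
    keys <- unique(paste(test_used$winter, test_used$month, sep = "_"))
    maps <- lapply(stats::setNames(keys, keys), function(key) {
      rp <- predict_rp(m, snow_by_key[[key]], canopy, dist_fs, dist_floor_m)
      if (is.null(extent)) rp else mask_surface(rp, extent)
    })
    v <- validate_map_use(maps, test_used, n_bins)
    taus[f] <- v$tau; ps[f] <- v$p
  }
  structure(list(per_fold_tau = taus, per_fold_p = ps, mean_tau = mean(taus),
                 n_bins = n_bins, k_folds = k, mode = mode),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s %d-fold validation: mean tau %.3f (folds %s)\n",
              x$mode, x$k_folds, x$mean_tau,
              paste(sprintf("%.2f", x$per_fold_tau), collapse = ", ")))
  invisible(x)
}
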