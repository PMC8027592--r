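#' Pooled quantile bin edges for Rp maps
#'
#' Computes the `n_bins`-quantile class edges from the pooled cell values
#' of a set of Rp maps (linear-interpolation quantile convention). The
#' pooled scheme — established once from the contemporary model's
#' predictions across the whole study — is reused for every map so bins
#' mean the same thing in every comparison; `-Inf`/`+Inf` sentinels route
#' out-of-range values into the end bins.
#'
#' @param rp_maps list of `rp_map` objects (or `grid_raster`s).
#' @param n_bins number of quantile classes (default 10).
#' @return numeric vector of `n_bins + 1` edges.
#' @export
pooled_quantile_edges <- function(rp_maps, n_bins = 10) {
  if (length(rp_maps) < 1L) stop("at least one map is required")
  pooled <- unlist(lapply(rp_maps, function(m) {
    r <- if (inherits(m, "rp_map")) m$raster else m
    finite_values(r)
  }))
  if (length(unique(pooled)) < n_bins)
    stop("too few distinct pooled values for the requested number of bins")
  edges <- stats::quantile(pooled, probs = seq_len(n_bins - 1) / n_bins,
                           names = FALSE)
  if (any(diff(edges) <= 0))
    stop("degenerate pooled quantiles: repeated edge values")
  c(-Inf, edges, Inf)
}

#' Bin an Rp map into quantile classes
#'
#' Cellwise right-closed interval lookup: a value lands in bin `i` iff
#' `edge[i] < v <= edge[i+1]` (a value equal to an interior edge goes to
#' the lower bin).
#'
#' @param rp an `rp_map` (or `grid_raster`).
#' @param edges edge vector from [pooled_quantile_edges()].
#' @return a `binned_map`: `raster` (integer bins 1..n_bins), `edges`,
#'   `n_bins`, plus `month`/`winter`/`label` metadata when present.
#' @export
bin_map <- function(rp, edges) {
  r <- if (inherits(rp, "rp_map")) rp$raster else rp
  n_bins <- length(edges) - 1L
  v <- r$values
  bins <- matrix(findInterval(v, edges, left.open = TRUE,
                              rightmost.closed = TRUE),
                 nrow(v), ncol(v))
  bins[!is.finite(v)] <- NA_integer_
  structure(list(
    raster = grid_raster(bins, r$x_origin, r$y_origin, r$cell_size, r$nodata),
    edges = edges, n_bins = n_bins,
    month = if (inherits(rp, "rp_map")) rp$month else NA,
    winter = if (inherits(rp, "rp_map")) rp$winter else NA,
    label = if (inherits(rp, "rp_map")) rp$label else NA
  ), class = "binned_map")
}

#' Random comparison points in the intersection of two home ranges
#'
#' Uniform points within `mask(A) & mask(B)`; a comparison batch reuses
#' the same point set for every map pair so kappas are comparable across
#' categories.
#'
#' @param polyA,polyB `home_range` objects on aligned grids.
#' @param n number of points (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame with `x`, `y`.
#' @export
sample_intersection_points <- function(polyA, polyB, n = 1000, seed = 1) {
  stopifnot_aligned(polyA$mask, polyB$mask)
  inter <- polyA$mask
  inter$values <- (polyA$mask$values == 1 & polyB$mask$values == 1) * 1
  if (!any(inter$values == 1)) stop("home-range intersection is empty")
  sample_available(structure(list(mask = inter, isopleth_level = NA,
                                  bandwidth = NA), class = "home_range"),
                   n, seed = seed)
}

#' Rank-disagreement-weighted Cohen's kappa
#'
#' Chance-corrected agreement between two binned-map samples with linear
#' disagreement weights `v_ij = |i - j| / (n_bins - 1)`:
#' `kappa = 1 - sum(v * observed) / sum(v * expected)` where `observed`
#' is the joint bin proportion matrix and `expected` the outer product of
#' its marginals. 1 for identical maps, about 0 for chance agreement, -1
#' for reverse-image maps.
#'
#' @param binsA,binsB integer bin vectors (values in 1..n_bins) at the
#'   same sampled points.
#' @param n_bins number of bin categories (default 10).
#' @param weights `"linear"` (default) or `"quadratic"` disagreement
#'   growth with rank distance.
#' @return kappa (numeric scalar).
#' @export
weighted_kappa <- function(binsA, binsB, n_bins = 10, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(binsA) != length(binsB)) stop("bin vectors must have equal length")
  if (length(binsA) < 2L) stop("need at least two points")
  if (any(binsA < 1 | binsA > n_bins | binsB < 1 | binsB > n_bins))
    stop("bin values outside 1..n_bins")
  o <- table(factor(binsA, levels = seq_len(n_bins)),
             factor(binsB, levels = seq_len(n_bins))) / length(binsA)
  e <- outer(rowSums(o), colSums(o))
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), `-`)) / (n_bins - 1)
  v <- if (weights == "linear") d else d^2
  num <- sum(v * o); den <- sum(v * e)
  if (den == 0) {
    if (num == 0) return(1)  # all mass in one identical cell
    stop("degenerate marginals: expected disagreement is zero")
  }
  1 - num / den
}

#' Compare kappa coefficients across comparison categories
#'
#' One-way ANOVA of the kappa coefficients of one month across the
#' comparison categories (year-to-year within each period/scenario and
#' inter-decadal), followed by Tukey HSD post-hoc tests with the usual
#' significance stars.
#'
#' @param records data.frame of kappa records with columns `month`,
#'   `category`, `kappa` (see [compare_rp_maps()]).
#' @param month month label to analyse.
#' @return list with `anova` (`F`, `p`, `df_between`, `df_within`) and
#'   `tukey` (data.frame: `pair`, `diff`, `p_adj`, `stars`).
#' @export
compare_categories <- function(records, month) {
  rec <- records[records$month == month, , drop = FALSE]
  counts <- table(rec$category)
  ok <- names(counts)[counts >= 2]
  if (length(ok) < 2)
    stop(sprintf("insufficient replication in month %s (categories with >= 2 records: %s)",
                 month, paste(ok, collapse = ", ")))
  rec <- rec[rec$category %in% ok, , drop = FALSE]
  rec$category <- factor(rec$category)
  if (stats::var(rec$kappa) == 0) {
    # no variation at all: no between-group signal, nothing significant
    pairs <- utils::combn(levels(rec$category), 2,
                          function(p) paste(p[2], p[1], sep = "-"))
    return(list(
      anova = list(F = 0, p = 1, df_between = nlevels(rec$category) - 1L,
                   df_within = nrow(rec) - nlevels(rec$category)),
      tukey = data.frame(pair = pairs, diff = 0, p_adj = 1, stars = "",
                         row.names = NULL)
    ))
  }
  fit <- stats::aov(kappa ~ category, data = rec)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$category
  stars <- cut(tk[, "p adj"], breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  list(
    anova = list(F = s[1, "F value"], p = s[1, "Pr(>F)"],
                 df_between = s[1, "Df"], df_within = s[2, "Df"]),
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], stars = as.character(stars),
                       row.names = NULL)
  )
}

#' Pairwise kappa comparison of monthly Rp maps
#'
#' For each month, evaluates every within-category year pair (and every
#' cross-period pair for the inter-decadal category) at a shared set of
#' random points inside the intersection of the two periods' home ranges,
#' using one pooled bin scheme for all maps.
#'
#' @param rp_by_cat named list: for each category label, a named list of
#'   `rp_map`s keyed `"<winter>_<month>"`.
#' @param inter_pair character vector of two category names whose maps are
#'   compared across categories as `"inter_decadal"`, or `NULL`.
#' @param edges pooled bin edges ([pooled_quantile_edges()]).
#' @param points data.frame of shared comparison points (`x`, `y`).
#' @param months months to compare.
#' @return data.frame of kappa records: `month`, `year_pair`, `category`,
#'   `kappa`, `n_points`.
#' @export
compare_rp_maps <- function(rp_by_cat, inter_pair = NULL, edges, points,
                            months = winter_months()) {
  n_bins <- length(edges) - 1L
  bin_at_points <- function(rp) {
    findInterval(extract_at(rp$raster, points$x, points$y), edges,
                 left.open = TRUE, rightmost.closed = TRUE)
  }
  recs <- list()
  add <- function(month, pair, cat, kap) {
    recs[[length(recs) + 1L]] <<- data.frame(
      month = month, year_pair = pair, category = cat, kappa = kap,
      n_points = nrow(points))
  }
  for (m in months) {
    for (cat in names(rp_by_cat)) {
      maps <- rp_by_cat[[cat]]
      keys <- names(maps)[endsWith(names(maps), paste0("_", m))]
      if (length(keys) < 2L) next
      for (i in seq_along(keys)[-length(keys)]) for (j in (i + 1L):length(keys)) {
        kap <- weighted_kappa(bin_at_points(maps[[keys[i]]]),
                              bin_at_points(maps[[keys[j]]]), n_bins)
        add(m, paste(keys[i], keys[j], sep = " vs "), cat, kap)
      }
    }
    if (!is.null(inter_pair)) {
      ka <- names(rp_by_cat[[inter_pair[1]]])
      kb <- names(rp_by_cat[[inter_pair[2]]])
      ka <- ka[endsWith(ka, paste0("_", m))]
      kb <- kb[endsWith(kb, paste0("_", m))]
      for (i in ka) for (j in kb) {
        kap <- weighted_kappa(bin_at_points(rp_by_cat[[inter_pair[1]]][[i]]),
                              bin_at_points(rp_by_cat[[inter_pair[2]]][[j]]),
                              n_bins)
        add(m, paste(i, j, sep = " vs "), "inter_decadal", kap)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Subtraction map of two binned Rp maps
#'
#' Cellwise `later_bin - earlier_bin` on maps binned with the same pooled
#' edges; values range from `-(n_bins - 1)` (strong preference in the
#' earlier year) to `+(n_bins - 1)` (strong preference in the later year).
#'
#' @param later,earlier `binned_map`s with identical edges, aligned.
#' @return an integer-valued `grid_raster` of bin differences.
#' @export
subtraction_map <- function(later, earlier) {
  if (!isTRUE(all.equal(later$edges, earlier$edges)))
    stop("maps binned on different scales")
  stopifnot_aligned(later$raster, earlier$raster)
  d <- later$raster$values - earlier$raster$values
  grid_raster(d, later$raster$x_origin, later$raster$y_origin,
              later$raster$cell_size, later$raster$nodata)
}
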