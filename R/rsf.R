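#' Linear 0-1 scaling
#'
#' Order-preserving affine rescaling of a numeric vector so its minimum
#' maps to 0 and its maximum to 1; the second step of the relative
#' probability-of-use prediction.
#'
#' @param values numeric vector with at least one finite value.
#' @return list with `values` (rescaled, NA preserved), `degenerate`
#'   (TRUE when all finite inputs are equal; output is all 0 then),
#'   `min`, `max` (the pre-scale extrema).
#' @export
lin_scale <- function(values) {
  fin <- is.finite(values)
  if (!any(fin)) stop("lin_scale needs at least one finite value")
  lo <- min(values[fin]); hi <- max(values[fin])
  if (hi == lo) {
    out <- values
    out[fin] <- 0
    return(list(values = out, degenerate = TRUE, min = lo, max = hi))
  }
  list(values = (values - lo) / (hi - lo), degenerate = FALSE, min = lo, max = hi)
}

#' Subsample telemetry to one fix per animal-day
#'
#' Randomly keeps exactly one fix per (animal, date), the standard
#' autocorrelation-reduction step before a used/available fit.
#'
#' @param relocations data.frame with `animal_id` and `date` columns.
#' @param seed integer RNG seed.
#' @return subset of `relocations`, one row per animal-day.
#' @export
subsample_one_per_animal_day <- function(relocations, seed = 1) {
  set.seed(derive_seed(seed, "subsample"))
  key <- interaction(relocations$animal_id, relocations$date, drop = TRUE)
  shuffled <- sample.int(nrow(relocations))
  keep <- shuffled[!duplicated(key[shuffled])]
  relocations[sort(keep), , drop = FALSE]
}

#' Sample available points within a home range
#'
#' Uniform sampling over the polygon's cells (cell uniform, position
#' uniform within the cell) — the available (case = 0) side of the
#' used/available design.
#'
#' @param polygon a `home_range` from [kde_isopleth()].
#' @param n number of points.
#' @param seed integer RNG seed.
#' @return data.frame with columns `x`, `y`.
#' @export
sample_available <- function(polygon, n, seed = 1) {
  mask <- polygon$mask
  cells <- which(mask$values == 1)
  if (length(cells) == 0L) stop("home-range polygon is empty")
  if (n < 1) stop("n must be >= 1")
  set.seed(derive_seed(seed, "available"))
  pick <- sample.int(length(cells), n, replace = TRUE)
  rows <- ((cells[pick] - 1L) %% nrow(mask$values)) + 1L
  cols <- ((cells[pick] - 1L) %/% nrow(mask$values)) + 1L
  cs <- mask$cell_size
  data.frame(
    x = mask$x_origin + (cols - 1L) * cs + stats::runif(n) * cs,
    y = mask$y_origin + (rows - 1L) * cs + stats::runif(n) * cs
  )
}

#' Feeding-site proximity raster
#'
#' Reciprocal of the (floored) distance-to-nearest-feeding-site surface:
#' `prox = 1 / max(dist, dist_floor_m)`. The floor keeps the covariate
#' finite at the sites themselves; it defaults to half the cell size.
#'
#' @param dist_fs `grid_raster` of distances (m).
#' @param dist_floor_m floor distance (m).
#' @return `grid_raster` of proximities (1/m).
#' @export
proximity_raster <- function(dist_fs, dist_floor_m = dist_fs$cell_size / 2) {
  grid_raster(1 / pmax(dist_fs$values, dist_floor_m),
              dist_fs$x_origin, dist_fs$y_origin, dist_fs$cell_size,
              dist_fs$nodata)
}

#' Attach RSF covariates to points
#'
#' Reads canopy cover and snow depth at each point's containing cell and
#' derives proximity (`1/max(dist, dist_floor_m)`) and the
#' snow-by-proximity interaction (`sd * prox`).
#'
#' @param points data.frame with `x`, `y` (m); all points share the given
#'   snow layer (available points inherit the month of their paired used
#'   point).
#' @param snow `grid_raster` of monthly mean snow depth (cm).
#' @param canopy aligned 0/1 `grid_raster`.
#' @param dist_fs aligned `grid_raster` of feeding-site distances (m).
#' @param dist_floor_m proximity floor (m), default half the cell size.
#' @return data.frame with columns `cc`, `sd`, `prox`, `inter` (row order
#'   preserved).
#' @export
attach_covariates <- function(points, snow, canopy, dist_fs,
                              dist_floor_m = snow$cell_size / 2) {
  stopifnot_aligned(snow, canopy, dist_fs)
  cc <- extract_at(canopy, points$x, points$y)
  sd <- extract_at(snow, points$x, points$y)
  dist <- extract_at(dist_fs, points$x, points$y)
  prox <- 1 / pmax(dist, dist_floor_m)
  data.frame(cc = cc, sd = sd, prox = prox, inter = sd * prox)
}

#' Build the used/available design table
#'
#' For each (winter, month) group of used points, samples the same number
#' of available points from the period's home-range polygon (1:1 ratio)
#' and attaches that month's covariates to both; available points inherit
#' the month (and snow layer) of their paired used group.
#'
#' @param used data.frame of used fixes (one per animal-day) with
#'   `animal_id`, `date`, `month`, `winter`, `x`, `y`, `period`.
#' @param polygon the period's `home_range`.
#' @param snow_by_key named list of monthly snow rasters keyed
#'   `"<winter>_<month>"`.
#' @param canopy,dist_fs aligned covariate rasters.
#' @param dist_floor_m proximity floor (m).
#' @param seed integer RNG seed.
#' @return a `uaa_design` data.frame: `case` (1 used / 0 available), `cc`,
#'   `sd`, `prox`, `inter`, `animal_id`, `month`, `winter`, `period`,
#'   `x`, `y`.
#' @export
build_uaa_design <- function(used, polygon, snow_by_key, canopy, dist_fs,
                             dist_floor_m = canopy$cell_size / 2, seed = 1) {
  keys <- unique(paste(used$winter, used$month, sep = "_"))
  missing <- setdiff(keys, names(snow_by_key))
  if (length(missing))
    stop(sprintf("no snow layer for: %s", paste(missing, collapse = ", ")))
  parts <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    key <- keys[i]
    grp <- used[paste(used$winter, used$month, sep = "_") == key, , drop = FALSE]
    snow <- snow_by_key[[key]]
    avail <- sample_available(polygon, nrow(grp),
                              seed = derive_seed(seed, paste("avail", key)))
    u <- cbind(case = 1,
               attach_covariates(grp, snow, canopy, dist_fs, dist_floor_m),
               animal_id = grp$animal_id, month = grp$month,
               winter = grp$winter, period = grp$period,
               x = grp$x, y = grp$y)
    a <- cbind(case = 0,
               attach_covariates(avail, snow, canopy, dist_fs, dist_floor_m),
               animal_id = NA_character_, month = grp$month[1],
               winter = grp$winter[1], period = grp$period[1],
               x = avail$x, y = avail$y)
    parts[[i]] <- rbind(u, a)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("uaa_design", "data.frame")
  out
}

#' Fit the used/available logistic RSF
#'
#' Maximum-likelihood logistic regression of `case` on canopy cover, snow
#' depth, feeding-site proximity and the snow-by-proximity interaction,
#' with intercept. Standard errors come from the observed information
#' matrix. The intercept is estimated but excluded from prediction (the
#' exponential RSF has none; linear scaling absorbs it).
#'
#' @param design a `uaa_design` (or data.frame with `case`, `cc`, `sd`,
#'   `prox`, `inter`).
#' @return an `rsf_model`: `beta`, `se` (named cc/sd/prox/inter),
#'   `intercept`, `loglik`, `converged`, `n_used`, `n_available`.
#' @export
fit_rsf <- function(design) {
  if (length(unique(design$case)) < 2L)
    stop("design must contain both used and available rows")
  for (v in c("cc", "sd", "prox", "inter")) {
    if (length(unique(design[[v]])) < 2L)
      stop(sprintf("covariate '%s' is constant", v))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(case ~ cc + sd + prox + inter, family = stats::binomial(),
               data = design, control = stats::glm.control(epsilon = 1e-10,
                                                           maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  if (sep_warn && any(abs(co[-1, "Estimate"] / pmax(co[-1, "Std. Error"], 1e-300)) > 50
                      | co[-1, "Std. Error"] > 1e3 * abs(co[-1, "Estimate"]) + 1e3))
    stop("separation detected: a covariate perfectly predicts case status")
  nm <- c(cc = "cc", sd = "sd", prox = "prox", inter = "inter")
  structure(list(
    beta = stats::setNames(co[nm, "Estimate"], names(nm)),
    se = stats::setNames(co[nm, "Std. Error"], names(nm)),
    intercept = co["(Intercept)", "Estimate"],
    loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged,
    n_used = sum(design$case == 1),
    n_available = sum(design$case == 0)
  ), class = "rsf_model")
}

#' @export
print.rsf_model <- function(x, ...) {
  cat(sprintf("rsf_model (%d used / %d available, logLik %.1f%s)\n",
              x$n_used, x$n_available, x$loglik,
              if (x$converged) "" else ", NOT converged"))
  print(data.frame(beta = x$beta, se = x$se))
  invisible(x)
}

#' Predict the relative probability-of-use surface
#'
#' Computes `w = exp(b_cc*CC + b_sd*SD + b_prox*prox + b_inter*SD*prox)`
#' cellwise (no intercept) and linearly rescales it to `[0, 1]` over the
#' finite cells of the prediction extent.
#'
#' @param model an `rsf_model` (or anything with a named `beta` vector).
#' @param snow,canopy,dist_fs aligned covariate rasters.
#' @param dist_floor_m proximity floor (m).
#' @param month,winter,label metadata carried on the map.
#' @return an `rp_map`: `raster` (`grid_raster` in `[0, 1]`), `month`,
#'   `winter`, `label`, `scaling_min`, `scaling_max`, `degenerate`.
#' @export
predict_rp <- function(model, snow, canopy, dist_fs,
                       dist_floor_m = snow$cell_size / 2,
                       month = NA, winter = NA, label = NA) {
  stopifnot_aligned(snow, canopy, dist_fs)
  b <- model$beta
  prox <- 1 / pmax(dist_fs$values, dist_floor_m)
  lp <- b[["cc"]] * canopy$values + b[["sd"]] * snow$values +
    b[["prox"]] * prox + b[["inter"]] * snow$values * prox
  w <- exp(lp - max(lp[is.finite(lp)]))  # constant offset; removed by scaling
  sc <- lin_scale(as.vector(w))
  if (sc$degenerate)
    warning("degenerate prediction: constant selection surface, map set to 0")
  structure(list(
    raster = grid_raster(matrix(sc$values, nrow(w), ncol(w)),
                         snow$x_origin, snow$y_origin, snow$cell_size,
                         snow$nodata),
    month = month, winter = winter, label = label,
    scaling_min = sc$min, scaling_max = sc$max, degenerate = sc$degenerate
  ), class = "rp_map")
}

#' @export
print.rp_map <- function(x, ...) {
  cat(sprintf("rp_map %s %s [%s]%s\n", x$winter, x$month, x$label,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
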