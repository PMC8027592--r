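#' Derive a stage seed from a master seed
#'
#' Deterministic per-stage streams: the stage label is hashed together with
#' the master seed so every pipeline stage gets an independent but
#' reproducible seed below 2^31.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483563) + 1L
}

#' Scenario configuration for snow regimes
#'
#' A scenario shifts the effective snowline upslope by `snowline_shift_m`
#' and rescales depths by `snow_scale`, standing in for progressively
#' warmer snow regimes. The historical regime is the reference: shift 0,
#' scale 1.
#'
#' @param label one of `"historical"`, `"contemporary"`, `"intermediate"`,
#'   `"severe"`.
#' @param snowline_shift_m upslope snowline displacement (m, `>= 0`).
#' @param snow_scale multiplicative depth factor in (0, 1].
#' @return a `scenario_config` object.
#' @export
scenario_config <- function(label = c("historical", "contemporary",
                                      "intermediate", "severe"),
                            snowline_shift_m = NULL, snow_scale = NULL) {
  label <- match.arg(label)
  defaults <- list(
    historical   = list(shift = 0,   scale = 1),
    contemporary = list(shift = 150, scale = 1),
    intermediate = list(shift = 300, scale = 0.85),
    severe       = list(shift = 600, scale = 0.70)
  )[[label]]
  if (is.null(snowline_shift_m)) snowline_shift_m <- defaults$shift
  if (is.null(snow_scale)) snow_scale <- defaults$scale
  if (label == "historical" && (snowline_shift_m != 0 || snow_scale != 1))
    stop("the historical scenario has shift 0 and scale 1 by definition")
  if (snowline_shift_m < 0) stop("snowline_shift_m must be >= 0")
  if (snow_scale <= 0 || snow_scale > 1) stop("snow_scale must be in (0, 1]")
  structure(list(label = label, snowline_shift_m = snowline_shift_m,
                 snow_scale = snow_scale),
            class = "scenario_config")
}

# bilinear upsample of a coarse matrix to nr x nc (correlated noise field)
upsample_bilinear <- function(coarse, nr, nc) {
  ry <- seq(1, nrow(coarse), length.out = nr)
  rx <- seq(1, ncol(coarse), length.out = nc)
  y0 <- pmin(floor(ry), nrow(coarse) - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(coarse) - 1L); fx <- rx - x0
  a <- coarse[y0, x0, drop = FALSE]; b <- coarse[y0, x0 + 1L, drop = FALSE]
  c_ <- coarse[y0 + 1L, x0, drop = FALSE]; d <- coarse[y0 + 1L, x0 + 1L, drop = FALSE]
  FX <- matrix(fx, nr, nc, byrow = TRUE); FY <- matrix(fy, nr, nc)
  a * (1 - FX) * (1 - FY) + b * FX * (1 - FY) + c_ * (1 - FX) * FY + d * FX * FY
}

#' Generate a synthetic valley DEM
#'
#' A deterministic valley-to-ridge ramp (lowest along the central
#' west-east valley axis, rising towards the north and south edges) plus
#' seeded spatially correlated noise, clipped to `[elev_min_m, elev_max_m]`.
#' Defaults emulate an alpine valley spanning roughly 400-3500 m.
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param cell_size cell edge (m).
#' @param elev_min_m,elev_max_m elevation range (m), `elev_min_m < elev_max_m`.
#' @param roughness standard deviation of the correlated noise (m); 0 gives
#'   a purely deterministic ramp.
#' @param seed integer RNG seed.
#' @return a `grid_raster` DEM.
#' @export
generate_dem <- function(nrow = 100, ncol = 100, cell_size = 100,
                         elev_min_m = 400, elev_max_m = 3500,
                         roughness = 120, seed = 1) {
  if (nrow < 1 || ncol < 1) stop("grid dimensions must be positive")
  if (elev_min_m >= elev_max_m) stop("elev_min_m must be below elev_max_m")
  mid <- (nrow + 1) / 2
  ramp <- abs(seq_len(nrow) - mid) / max(mid - 1, 1)  # 0 at valley axis, 1 at edges
  base <- elev_min_m + (elev_max_m - elev_min_m) * matrix(ramp, nrow, ncol)
  if (roughness > 0) {
    set.seed(seed)
    coarse <- matrix(stats::rnorm(9 * 9, 0, roughness), 9, 9)
    base <- base + upsample_bilinear(coarse, nrow, ncol)
  }
  base <- pmin(pmax(base, elev_min_m), elev_max_m)
  grid_raster(base, 0, 0, cell_size)
}

#' Default snow-generator parameters
#'
#' Month-indexed (Nov-Apr) snowline elevations, base depths, interannual
#' mean shifts and interannual standard deviations, plus the
#' depth-per-elevation lapse and the daily noise level. Two presets encode
#' the study's two snow regimes: `"historical"` (interannually variable in
#' every month) and `"contemporary"` (snow-scarce and interannually stable
#' in December, January and April; still variable mid-winter).
#'
#' @param period `"historical"` or `"contemporary"`.
#' @return a named parameter list.
#' @export
snow_params <- function(period = c("historical", "contemporary")) {
  period <- match.arg(period)
  m <- winter_months()
  p <- list(
    lapse_cm_per_m = 0.08,
    snowline_m = stats::setNames(c(1800, 1400, 1000, 950, 1100, 1600), m),
    base_depth_cm = stats::setNames(c(5, 15, 30, 35, 25, 8), m),
    interannual_shift_cm = stats::setNames(rep(0, 6), m),
    interannual_sd_cm = stats::setNames(rep(15, 6), m),
    daily_noise_sd_cm = 3
  )
  if (period == "contemporary") {
    # scarcer, near-constant early/late winter snow in recent years
    p$interannual_shift_cm[c("Dec", "Jan", "Apr")] <- -12
    p$interannual_sd_cm[c("Dec", "Jan", "Apr")] <- 1.5
  }
  p
}

#' Generate a winter of daily snow-depth layers
#'
#' Daily depth at a cell is
#' `max(0, lapse * (elev - snowline(month) - shift) + base(month) +
#' interannual(month, winter) + noise(day)) * snow_scale`,
#' with the snowline lowest in mid-winter (Jan-Mar), a seeded interannual
#' depth anomaly per month drawn from the regime's per-month variance, and
#' day-to-day scalar noise. Construction is monotone in elevation (zero
#' daily noise across cells), monotone decreasing in `snowline_shift_m`,
#' and a pure function of its arguments and seed.
#'
#' @param dem a `grid_raster` DEM (m).
#' @param winter winter label (e.g. `"1999"`), entering the interannual draw.
#' @param months months to simulate, subset of [winter_months()].
#' @param scenario a [scenario_config()].
#' @param params parameter list from [snow_params()].
#' @param days_per_month days simulated per month.
#' @param seed integer RNG seed.
#' @return list with `layers` (list of daily `grid_raster`, cm) and
#'   `month` (character label per layer).
#' @export
generate_snow_days <- function(dem, winter, months = winter_months(),
                               scenario = scenario_config("historical"),
                               params = snow_params("historical"),
                               days_per_month = 30, seed = 1) {
  bad <- setdiff(months, winter_months())
  if (length(bad)) stop(sprintf("invalid months: %s", paste(bad, collapse = ", ")))
  layers <- list(); labels <- character(0)
  elev <- dem$values
  for (m in months) {
    set.seed(derive_seed(seed, paste("snow", winter, m)))
    anom <- stats::rnorm(1, params$interannual_shift_cm[[m]],
                         params$interannual_sd_cm[[m]])
    day_noise <- stats::rnorm(days_per_month, 0, params$daily_noise_sd_cm)
    for (d in seq_len(days_per_month)) {
      depth <- params$lapse_cm_per_m *
        (elev - params$snowline_m[[m]] - scenario$snowline_shift_m) +
        params$base_depth_cm[[m]] + anom + day_noise[d]
      depth <- pmax(depth, 0) * scenario$snow_scale
      layers[[length(layers) + 1L]] <-
        grid_raster(depth, dem$x_origin, dem$y_origin, dem$cell_size, dem$nodata)
      labels <- c(labels, m)
    }
  }
  list(layers = layers, month = labels)
}

#' Generate a binary canopy-cover raster
#'
#' Forest (1) below the treeline with patchy, spatially correlated
#' openings; open (0) above the treeline. Emulates a reclassified
#' land-cover map (closed forest classes = 1, all else = 0).
#'
#' @param dem a `grid_raster` DEM (m).
#' @param treeline_m elevation above which cells are open (default 2000 m).
#' @param forest_prob approximate forested fraction below the treeline.
#' @param seed integer RNG seed.
#' @return an aligned 0/1 `grid_raster`.
#' @export
generate_canopy <- function(dem, treeline_m = 2000, forest_prob = 0.7, seed = 1) {
  set.seed(derive_seed(seed, "canopy"))
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  noise <- upsample_bilinear(matrix(stats::rnorm(12 * 12), 12, 12), nr, nc)
  cutoff <- stats::quantile(noise, 1 - forest_prob)
  cc <- (noise >= cutoff & dem$values < treeline_m) * 1
  grid_raster(cc, dem$x_origin, dem$y_origin, dem$cell_size, dem$nodata)
}

#' Place supplemental feeding sites
#'
#' Draws `n_sites` cell-centre points uniformly from the cells of
#' `valid_mask`, enforcing a minimum pairwise spacing by rejection; errors
#' if the spacing is infeasible after bounded retries.
#'
#' @param n_sites number of sites.
#' @param valid_mask `grid_raster` with 1 at admissible cells.
#' @param min_spacing_m minimum pairwise distance (m).
#' @param seed integer RNG seed.
#' @return data.frame with columns `x`, `y` (m).
#' @export
place_feeding_sites <- function(n_sites, valid_mask, min_spacing_m = 0, seed = 1) {
  cells <- which(valid_mask$values == 1, arr.ind = TRUE)
  if (nrow(cells) < n_sites) stop("valid mask has fewer cells than requested sites")
  set.seed(derive_seed(seed, "feeding_sites"))
  cx <- valid_mask$x_origin + (cells[, "col"] - 0.5) * valid_mask$cell_size
  cy <- valid_mask$y_origin + (cells[, "row"] - 0.5) * valid_mask$cell_size
  for (attempt in seq_len(50L)) {
    ord <- sample(nrow(cells))
    x <- numeric(0); y <- numeric(0)
    for (i in ord) {
      if (length(x) == 0L ||
          min((cx[i] - x)^2 + (cy[i] - y)^2) >= min_spacing_m^2) {
        x <- c(x, cx[i]); y <- c(y, cy[i])
        if (length(x) == n_sites) return(data.frame(x = x, y = y))
      }
    }
  }
  stop("could not place sites at the requested spacing after bounded retries")
}
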