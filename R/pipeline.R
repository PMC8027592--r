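#' Default experiment configuration
#'
#' The study conditions of the synthetic two-period fixture: an alpine
#' valley grid, a historical period (3 winters, 20 feeding sites,
#' interannually variable snow in every month) and a contemporary period
#' (3 winters, 95 feeding sites, snow-scarce and interannually stable in
#' December, January and April), plus two forecast snow scenarios
#' (intermediate and severe snowline shifts) predicted with the
#' contemporary model. Analysis constants follow the method: 10 quantile
#' bins, 5 folds, 1000 shared comparison points, Nov-Apr months, proximity
#' floor of half a cell.
#'
#' @param master_seed integer; every stage seed is derived from it.
#' @return a `run_config` list.
#' @export
default_run_config <- function(master_seed = 1) {
  grid <- list(nrow = 80, ncol = 80, cell_size = 100,
               elev_min_m = 400, elev_max_m = 3500, roughness = 120)
  list(
    master_seed = as.integer(master_seed),
    grid = grid,
    months = winter_months(),
    snow_days_per_month = 30,
    telemetry_days_per_month = 10,
    n_bins = 10, k_folds = 5, n_compare_points = 1000,
    dist_floor_m = grid$cell_size / 2,
    site_elev_max_m = 1500,
    upslope_band_m = 1500,
    truth = truth_rsf(),
    periods = list(
      historical = list(
        winters = c("1999", "2000", "2001"), n_sites = 20,
        min_spacing_m = 400, n_animals = 24, fixes_per_day = 1,
        scenario = scenario_config("historical"),
        snow = snow_params("historical")
      ),
      contemporary = list(
        winters = c("2013", "2014", "2015"), n_sites = 95,
        min_spacing_m = 150, n_animals = 23, fixes_per_day = 3,
        scenario = scenario_config("contemporary"),
        snow = snow_params("contemporary")
      )
    ),
    scenarios = list(
      intermediate = scenario_config("intermediate"),
      severe = scenario_config("severe")
    )
  )
}

# monthly mean snow + cover days for a set of winters under one regime
build_snow <- function(dem, winters, months, scenario, params,
                       days_per_month, seed) {
  snow_by_key <- list()
  cover_by_winter <- list()
  for (w in winters) {
    daily <- generate_snow_days(dem, w, months, scenario, params,
                                days_per_month, seed = seed)
    means <- monthly_mean_snow(daily$layers, daily$month)
    for (m in names(means)) snow_by_key[[paste(w, m, sep = "_")]] <- means[[m]]
    cover_by_winter[[w]] <- snow_cover_days(daily$layers)
  }
  list(snow_by_key = snow_by_key, cover_by_winter = cover_by_winter)
}

#' Run the full winter space-use experiment
#'
#' Executes the whole pipeline on the synthetic fixture: landscape and
#' snow generation, feeding-site placement, 3D path distances, telemetry
#' simulation from the ground-truth RSF, one-fix-per-animal-day
#' subsampling, 99% kernel home ranges, used/available design and
#' period-specific RSF fits, monthly Rp prediction for both periods and
#' both forecast scenarios, ROC/k-fold/temporal validation, pooled-bin
#' weighted-kappa map comparison with per-month ANOVA + Tukey tests,
#' subtraction maps, and scenario upslope summaries. Deterministic under
#' `config$master_seed`.
#'
#' @param config a configuration from [default_run_config()].
#' @param outdir optional directory; when given, tables, rasters, models
#'   and a manifest (with file hashes) are written there.
#' @return a list of all fitted objects and summary tables (see README).
#' @export
run_experiment <- function(config = default_run_config(), outdir = NULL) {
  seed <- config$master_seed
  g <- config$grid
  dem <- generate_dem(g$nrow, g$ncol, g$cell_size, g$elev_min_m, g$elev_max_m,
                      g$roughness, seed = derive_seed(seed, "dem"))
  canopy <- generate_canopy(dem, seed = derive_seed(seed, "canopy"))
  valley <- grid_raster((dem$values < config$site_elev_max_m) * 1,
                        dem$x_origin, dem$y_origin, dem$cell_size)

  periods <- names(config$periods)
  sites <- list(); dist_fs <- list(); prox <- list()
  snow <- list(); cover <- list()
  for (p in periods) {
    pc <- config$periods[[p]]
    sites[[p]] <- place_feeding_sites(pc$n_sites, valley, pc$min_spacing_m,
                                      seed = derive_seed(seed, paste("sites", p)))
    dist_fs[[p]] <- path_distance_3d(dem, sites[[p]])
    prox[[p]] <- proximity_raster(dist_fs[[p]], config$dist_floor_m)
    sn <- build_snow(dem, pc$winters, config$months, pc$scenario, pc$snow,
                     config$snow_days_per_month,
                     seed = derive_seed(seed, paste("snow", p)))
    snow[[p]] <- sn$snow_by_key
    cover[[p]] <- sn$cover_by_winter
  }

  # telemetry sampled from the ground truth over the whole landscape (the
  # exponential weights confine use to low elevations), then the
  # estimation path
  all_cells <- grid_raster(matrix(1, g$nrow, g$ncol), dem$x_origin,
                           dem$y_origin, dem$cell_size)
  relocs <- list(); used <- list(); polygons <- list()
  designs <- list(); models <- list()
  for (p in periods) {
    pc <- config$periods[[p]]
    covs <- lapply(snow[[p]], function(s) list(cc = canopy, sd = s, prox = prox[[p]]))
    relocs[[p]] <- simulate_relocations(
      config$truth, covs, all_cells, n_animals = pc$n_animals,
      days_per_month = config$telemetry_days_per_month,
      seed = derive_seed(seed, paste("reloc", p)),
      fixes_per_day = pc$fixes_per_day, period = p,
      animal_prefix = toupper(substr(p, 1, 1)))
    used[[p]] <- subsample_one_per_animal_day(
      relocs[[p]], seed = derive_seed(seed, paste("sub", p)))
    polygons[[p]] <- kde_isopleth(used[[p]], level = 0.99, grid = dem)
    designs[[p]] <- build_uaa_design(
      used[[p]], polygons[[p]], snow[[p]], canopy, dist_fs[[p]],
      config$dist_floor_m, seed = derive_seed(seed, paste("design", p)))
    models[[p]] <- fit_rsf(designs[[p]])
  }

  # monthly Rp maps: each period with its own model; forecast scenarios
  # with the contemporary model, sites and winters
  rp <- list()
  for (p in periods) {
    rp[[paste0("intra_", substr(p, 1, 1))]] <- lapply(
      stats::setNames(names(snow[[p]]), names(snow[[p]])), function(key) {
        parts <- strsplit(key, "_")[[1]]
        predict_rp(models[[p]], snow[[p]][[key]], canopy, dist_fs[[p]],
                   config$dist_floor_m, month = parts[2], winter = parts[1],
                   label = p)
      })
  }
  cc_cfg <- config$periods$contemporary
  scen_snow <- list(); scen_cover <- list()
  for (s in names(config$scenarios)) {
    sn <- build_snow(dem, cc_cfg$winters, config$months, config$scenarios[[s]],
                     cc_cfg$snow, config$snow_days_per_month,
                     seed = derive_seed(seed, "snow contemporary"))
    scen_snow[[s]] <- sn$snow_by_key
    scen_cover[[s]] <- sn$cover_by_winter
    rp[[paste0("intra_", substr(s, 1, 1))]] <- lapply(
      stats::setNames(names(sn$snow_by_key), names(sn$snow_by_key)), function(key) {
        parts <- strsplit(key, "_")[[1]]
        predict_rp(models$contemporary, sn$snow_by_key[[key]], canopy,
                   dist_fs$contemporary, config$dist_floor_m,
                   month = parts[2], winter = parts[1], label = s)
      })
  }

  # validation: ROC AUC, spatial k-fold, temporal hindcast of the
  # contemporary model onto the historical period's covariates and use
  validation <- list()
  for (p in periods) {
    validation[[p]] <- list(
      auc = roc_auc(models[[p]], designs[[p]]),
      kfold = kfold_validate(designs[[p]], snow[[p]], canopy, dist_fs[[p]],
                             config$dist_floor_m, k = config$k_folds,
                             n_bins = config$n_bins,
                             seed = derive_seed(seed, paste("kfold", p)),
                             extent = polygons[[p]])
    )
  }
  hind_maps <- lapply(
    stats::setNames(names(snow$historical), names(snow$historical)),
    function(key) {
      mask_surface(
        predict_rp(models$contemporary, snow$historical[[key]], canopy,
                   dist_fs$historical, config$dist_floor_m),
        polygons$historical)
    })
  hind_used <- used$historical[
    in_home_range(polygons$historical, used$historical$x, used$historical$y), ]
  validation$temporal <- validate_map_use(hind_maps, hind_used, config$n_bins)

  # map comparison: pooled contemporary-model bin scheme, shared points
  edges <- pooled_quantile_edges(rp$intra_c, config$n_bins)
  points <- sample_intersection_points(
    polygons$historical, polygons$contemporary, config$n_compare_points,
    seed = derive_seed(seed, "points"))
  kappa_records <- compare_rp_maps(rp, inter_pair = c("intra_h", "intra_c"),
                                   edges, points, config$months)
  anova_months <- setdiff(intersect(config$months, unique(kappa_records$month)),
                          "Nov")  # November excluded: low sample size
  anova <- lapply(stats::setNames(anova_months, anova_months),
                  function(m) compare_categories(kappa_records, m))

  # subtraction maps: low-snow minus high-snow winters within each period,
  # and severe scenario minus the contemporary winters, for Dec/Feb/Apr
  pick_pair <- function(cat) {
    keys <- names(rp[[cat]])
    winters <- sort(unique(sub("_.*", "", keys)))
    c(earlier = winters[1], later = winters[length(winters)])
  }
  subtraction <- list()
  for (cat in c("intra_h", "intra_c")) {
    pr <- pick_pair(cat)
    for (m in intersect(c("Dec", "Feb", "Apr"), config$months)) {
      ke <- paste(pr["earlier"], m, sep = "_"); kl <- paste(pr["later"], m, sep = "_")
      if (!is.null(rp[[cat]][[ke]]) && !is.null(rp[[cat]][[kl]])) {
        subtraction[[paste(cat, m, sep = "_")]] <- subtraction_map(
          bin_map(rp[[cat]][[kl]], edges), bin_map(rp[[cat]][[ke]], edges))
      }
    }
  }
  for (m in intersect(c("Dec", "Feb", "Apr"), config$months)) {
    w <- cc_cfg$winters[1]
    key <- paste(w, m, sep = "_")
    if (!is.null(rp$intra_s[[key]]) && !is.null(rp$intra_c[[key]])) {
      subtraction[[paste("severe_vs_contemporary", m, sep = "_")]] <-
        subtraction_map(bin_map(rp$intra_s[[key]], edges),
                        bin_map(rp$intra_c[[key]], edges))
    }
  }

  # scenario upslope summary: top-3-bin Rp area above the mid-elevation
  # band, and grid-total snow-cover days, per snow regime of increasing
  # snowline shift (contemporary < intermediate < severe)
  regimes <- c(list(contemporary = list(rp = rp$intra_c, cover = cover$contemporary,
                                        shift = cc_cfg$scenario$snowline_shift_m)),
               lapply(stats::setNames(names(config$scenarios), names(config$scenarios)),
                      function(s) list(rp = rp[[paste0("intra_", substr(s, 1, 1))]],
                                       cover = scen_cover[[s]],
                                       shift = config$scenarios[[s]]$snowline_shift_m)))
  high <- dem$values >= config$upslope_band_m
  scenario_summary <- do.call(rbind, lapply(names(regimes), function(nm) {
    rg <- regimes[[nm]]
    top_area <- mean(vapply(rg$rp, function(map) {
      bins <- bin_map(map, edges)$raster$values
      sum(bins >= config$n_bins - 2 & high)
    }, numeric(1)))
    data.frame(regime = nm, snowline_shift_m = rg$shift,
               top_bin_cells_upslope = top_area,
               total_cover_days = sum(vapply(rg$cover,
                                             function(cd) sum(cd$values),
                                             numeric(1))))
  }))

  result <- list(
    config = config, dem = dem, canopy = canopy, sites = sites,
    dist_fs = dist_fs, snow = snow, cover = cover, scen_snow = scen_snow,
    relocations = relocs, used = used, polygons = polygons,
    designs = designs, models = models, rp = rp, edges = edges,
    points = points, kappa_records = kappa_records, anova = anova,
    subtraction = subtraction, validation = validation,
    scenario_summary = scenario_summary
  )
  if (!is.null(outdir)) result$manifest <- write_experiment(result, outdir)
  result
}

#' Parameter-recovery benchmark
#'
#' Simulates telemetry from the ground-truth RSF under a single
#' winter-month covariate layer and runs the full estimation path
#' (one-fix-per-animal-day subsampling, 99% kernel home range, 1:1
#' used/available design, logistic fit). With a single layer the
#' availability normalizing constant is common to all points, so the
#' used/available logistic estimator of the exponential RSF is consistent
#' and recovered slopes should fall within sampling error of the truth;
#' this is the package's core correctness benchmark. (The pooled
#' multi-month fit of [run_experiment()] absorbs month-specific
#' normalizers into one intercept, as the published design does, at the
#' price of a small attenuation — see the methods vignette.)
#'
#' @param seed integer seed for every stage.
#' @param n_animals,days_per_month telemetry effort; the default yields
#'   4200 used points.
#' @param truth a [truth_rsf()].
#' @param month,winter covariate layer labels.
#' @param grid_nrow,grid_ncol,cell_size landscape grid.
#' @return list: `truth`, `model`, `design`, `used`, `polygon`, `snow`
#'   (named single-layer list), `canopy`, `dist_fs`, `dem`,
#'   `dist_floor_m`, and `z` (signed recovery z-scores per slope).
#' @export
recovery_experiment <- function(seed = 1, n_animals = 140, days_per_month = 30,
                                truth = truth_rsf(), month = "Feb",
                                winter = "1999", grid_nrow = 80,
                                grid_ncol = 80, cell_size = 100) {
  dem <- generate_dem(grid_nrow, grid_ncol, cell_size,
                      seed = derive_seed(seed, "dem"))
  canopy <- generate_canopy(dem, seed = derive_seed(seed, "canopy"))
  valley <- grid_raster((dem$values < 1500) * 1, dem$x_origin, dem$y_origin,
                        cell_size)
  sites <- place_feeding_sites(20, valley, 400, seed = derive_seed(seed, "sites"))
  dist_fs <- path_distance_3d(dem, sites)
  floor_m <- cell_size / 2
  prox <- proximity_raster(dist_fs, floor_m)
  daily <- generate_snow_days(dem, winter, month, days_per_month = 30,
                              seed = derive_seed(seed, "snow"))
  snow <- monthly_mean_snow(daily$layers, daily$month)[[month]]
  key <- paste(winter, month, sep = "_")
  snow_by_key <- stats::setNames(list(snow), key)
  full <- grid_raster(matrix(1, grid_nrow, grid_ncol), dem$x_origin,
                      dem$y_origin, cell_size)
  rel <- simulate_relocations(truth,
                              stats::setNames(list(list(cc = canopy, sd = snow,
                                                        prox = prox)), key),
                              full, n_animals = n_animals,
                              days_per_month = days_per_month,
                              seed = derive_seed(seed, "reloc"))
  used <- subsample_one_per_animal_day(rel, seed = derive_seed(seed, "sub"))
  polygon <- kde_isopleth(used, 0.99, dem)
  design <- build_uaa_design(used, polygon, snow_by_key, canopy, dist_fs,
                             floor_m, seed = derive_seed(seed, "design"))
  model <- fit_rsf(design)
  tr <- unlist(unclass(truth))[c("beta_cc", "beta_sd", "beta_prox", "beta_inter")]
  list(truth = truth, model = model, design = design, used = used,
       polygon = polygon, snow = snow_by_key, canopy = canopy,
       dist_fs = dist_fs, dem = dem, dist_floor_m = floor_m,
       z = stats::setNames((model$beta - tr) / model$se, names(model$beta)))
}

# write the main artifacts as text files and return a hashed manifest
write_experiment <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); stages <- character(0)
  put <- function(path, stage) {
    files <<- c(files, path); stages <<- c(stages, stage)
  }
  wa <- function(r, name, stage) {
    p <- file.path(outdir, name); write_ascii_grid(r, p); put(p, stage)
  }
  wc <- function(df, name, stage) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE); put(p, stage)
  }
  wa(result$dem, "dem.asc", "landscape")
  wa(result$canopy, "canopy.asc", "landscape")
  for (p in names(result$sites)) {
    wc(result$sites[[p]], sprintf("sites_%s.csv", p), "landscape")
    wa(result$dist_fs[[p]], sprintf("dist_fs_%s.asc", p), "landscape")
    wc(result$used[[p]], sprintf("used_%s.csv", p), "telemetry")
    wc(as.data.frame(result$designs[[p]]), sprintf("design_%s.csv", p), "design")
    m <- result$models[[p]]
    mp <- file.path(outdir, sprintf("model_%s.yaml", p))
    yaml::write_yaml(list(beta = as.list(m$beta), se = as.list(m$se),
                          intercept = m$intercept, loglik = m$loglik,
                          converged = m$converged, n_used = m$n_used,
                          n_available = m$n_available), mp)
    put(mp, "fit")
  }
  tp <- file.path(outdir, "truth.yaml")
  yaml::write_yaml(unclass(result$config$truth), tp); put(tp, "landscape")
  wc(result$kappa_records, "kappas.csv", "compare")
  anova_df <- do.call(rbind, lapply(names(result$anova), function(m) {
    a <- result$anova[[m]]$anova
    data.frame(month = m, F = a$F, p = a$p)
  }))
  wc(anova_df, "anova.csv", "compare")
  wc(result$scenario_summary, "scenario_summary.csv", "forecast")
  for (nm in names(result$subtraction))
    wa(result$subtraction[[nm]], sprintf("diff_%s.asc", nm), "compare")

  manifest <- data.frame(file = basename(files), stage = stages,
                         md5 = unname(tools::md5sum(files)))
  mp <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(list(master_seed = result$config$master_seed,
                        files = split(manifest, seq_len(nrow(manifest)))), mp)
  manifest
}
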