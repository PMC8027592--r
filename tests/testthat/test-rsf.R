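test_that("linear scaling maps extremes to 0 and 1 and preserves order", {
  expect_equal(lin_scale(c(2, 4, 6))$values, c(0, 0.5, 1))
  expect_equal(lin_scale(c(-3, 0, 9))$values, c(0, 0.25, 1))
  x <- rnorm(50)
  s <- lin_scale(x)
  expect_false(s$degenerate)
  expect_identical(order(s$values), order(x))
  d <- lin_scale(rep(3, 5))
  expect_true(d$degenerate)
  expect_equal(d$values, rep(0, 5))
  expect_error(lin_scale(rep(NA_real_, 3)), "finite")
})

test_that("one fix per animal-day subsampling counts and reproducibility", {
  rel <- expand.grid(animal_id = c("A", "B", "C"),
                     date = sprintf("d%02d", 1:10), fix = 1:8,
                     stringsAsFactors = FALSE)
  rel$x <- seq_len(nrow(rel)); rel$y <- rev(rel$x)
  out <- subsample_one_per_animal_day(rel, seed = 4)
  expect_equal(nrow(out), 30)
  expect_equal(anyDuplicated(paste(out$animal_id, out$date)), 0)

  out2 <- subsample_one_per_animal_day(rel, seed = 4)
  out3 <- subsample_one_per_animal_day(rel, seed = 5)
  expect_identical(out, out2)
  expect_false(identical(out$x, out3$x))

  single <- rel[rel$fix == 1, ]
  expect_identical(subsample_one_per_animal_day(single, seed = 1)$x, single$x)
})

test_that("available points are uniform within the home-range mask", {
  mask <- grid_raster(matrix(0, 8, 8), cell_size = 50)
  mask$values[3:6, 2:7] <- 1
  hr <- structure(list(mask = mask, isopleth_level = 0.99, bandwidth = NA),
                  class = "home_range")
  pts <- sample_available(hr, 50000, seed = 12)
  idx <- cell_index_at(mask, pts$x, pts$y)
  expect_true(all(mask$values[idx] == 1))
  counts <- table(paste(idx[, 1], idx[, 2]))
  expect_equal(length(counts), 24)
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
  empty <- structure(list(mask = grid_raster(matrix(0, 2, 2), cell_size = 1)),
                     class = "home_range")
  expect_error(sample_available(empty, 5), "empty")
})

test_that("covariate attachment applies the proximity floor and interaction", {
  snow <- grid_raster(matrix(c(0, 10, 20, 30, 40, 50, 60, 70, 80), 3, 3),
                      cell_size = 10)
  canopy <- grid_raster(matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3, 3),
                        cell_size = 10)
  dist <- grid_raster(matrix(c(0, 5, 10, 20, 40, 80, 160, 320, 640), 3, 3),
                      cell_size = 10)
  centers <- expand.grid(y = c(5, 15, 25), x = c(5, 15, 25))
  rows <- attach_covariates(centers, snow, canopy, dist, dist_floor_m = 5)
  # hand-computed: column-major over the 3x3 toy rasters
  expect_equal(rows$cc, c(1, 0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(rows$sd, seq(0, 80, by = 10))
  expect_equal(rows$prox, 1 / pmax(c(0, 5, 10, 20, 40, 80, 160, 320, 640), 5))
  expect_equal(rows$inter, rows$sd * rows$prox)
  # at a feeding site with a 5 m floor the proximity is 0.2 per metre
  expect_equal(rows$prox[1], 0.2)
  # zero snow kills the interaction regardless of distance
  expect_equal(rows$inter[rows$sd == 0], 0)
  expect_error(attach_covariates(data.frame(x = 99, y = 5), snow, canopy, dist),
               "outside")
})

test_that("logistic fit recovers simulated selection and scales like a likelihood", {
  rec <- recovery_experiment(seed = 3, n_animals = 40, days_per_month = 25)
  m <- rec$model
  expect_true(m$converged)
  expect_true(all(m$se > 0))
  expect_equal(m$n_used, m$n_available)
  expect_lt(m$beta[["sd"]], 0)
  expect_gt(m$beta[["prox"]], 0)
  # recovered slopes near truth at this effort (1000 used points)
  expect_true(all(abs(rec$z) < 4))

  # duplicating rows: identical estimates, SEs shrink by sqrt(2)
  d2 <- rbind(rec$design, rec$design)
  m2 <- fit_rsf(d2)
  expect_equal(m2$beta, m$beta, tolerance = 1e-6)
  expect_equal(m2$se, m$se / sqrt(2), tolerance = 1e-4)
})

test_that("degenerate designs are rejected", {
  d <- data.frame(case = rep(c(1, 0), each = 20),
                  cc = rep(c(1, 0), each = 20),  # perfect separation
                  sd = rnorm(40), prox = runif(40, 0.001, 0.02))
  d$inter <- d$sd * d$prox
  expect_error(fit_rsf(d), "separation")
  d_const <- d; d_const$cc <- 1
  expect_error(fit_rsf(d_const), "constant")
  d_one <- d[d$case == 1, ]
  expect_error(fit_rsf(d_one), "both used and available")
})

test_that("Rp prediction matches the hand-computed exponential form", {
  snow <- grid_raster(matrix(c(0, 20, 40, 60), 2, 2), cell_size = 10)
  canopy <- grid_raster(matrix(c(1, 0, 0, 1), 2, 2), cell_size = 10)
  dist <- grid_raster(matrix(c(10, 100, 1000, 10), 2, 2), cell_size = 10)
  model <- structure(list(beta = c(cc = 1, sd = -0.1, prox = 100, inter = 0)),
                     class = "rsf_model")
  rp <- predict_rp(model, snow, canopy, dist, dist_floor_m = 5)
  w <- exp(1 * canopy$values - 0.1 * snow$values + 100 / pmax(dist$values, 5))
  expected <- (w - min(w)) / (max(w) - min(w))
  expect_equal(rp$raster$values, expected, tolerance = 1e-12)
  expect_equal(min(rp$raster$values), 0)
  expect_equal(max(rp$raster$values), 1)
  expect_false(rp$degenerate)
})

test_that("Rp is invariant to constant offsets and degenerate when flat", {
  fx <- tiny_fixture(23)
  sn <- generate_snow_days(fx$dem, "2014", "Dec", days_per_month = 3, seed = 2)
  snow <- monthly_mean_snow(sn$layers, sn$month)$Dec
  model <- structure(list(beta = c(cc = 0.8, sd = -0.05, prox = 300, inter = 5)),
                     class = "rsf_model")
  rp1 <- predict_rp(model, snow, fx$canopy, fx$dist_fs, 50)
  shifted_canopy <- fx$canopy
  shifted_canopy$values <- shifted_canopy$values + 1  # adds beta_cc everywhere
  rp2 <- predict_rp(model, snow, shifted_canopy, fx$dist_fs, 50)
  expect_equal(rp1$raster$values, rp2$raster$values, tolerance = 1e-9)

  null_model <- structure(list(beta = c(cc = 0, sd = 0, prox = 0, inter = 0)),
                          class = "rsf_model")
  expect_warning(rp0 <- predict_rp(null_model, snow, fx$canopy, fx$dist_fs, 50),
                 "degenerate")
  expect_true(rp0$degenerate)
  expect_true(all(rp0$raster$values == 0))
})

test_that("with negative snow slope Rp is cellwise non-increasing in snow", {
  fx <- tiny_fixture(29)
  model <- structure(list(beta = c(cc = 0.5, sd = -0.08, prox = 200, inter = 0)),
                     class = "rsf_model")
  shallow <- grid_raster(matrix(10, 40, 40), cell_size = 100)
  deep <- grid_raster(matrix(35, 40, 40), cell_size = 100)
  # only SD varies between the two prediction stacks; compare unscaled order
  rp_sh <- predict_rp(model, shallow, fx$canopy, fx$dist_fs, 50)
  rp_dp <- predict_rp(model, deep, fx$canopy, fx$dist_fs, 50)
  # constant SD shift is absorbed by scaling: maps identical
  expect_equal(rp_sh$raster$values, rp_dp$raster$values, tolerance = 1e-9)
  # spatially varying deepening: deepened cells lose rank
  extra <- grid_raster(matrix(10, 40, 40), cell_size = 100)
  extra$values[1:20, ] <- 60
  rp_ex <- predict_rp(model, extra, fx$canopy, fx$dist_fs, 50)
  expect_true(all(rp_ex$raster$values[1:20, ] <= rp_sh$raster$values[1:20, ] + 1e-9))
})

test_that("design construction keeps the 1:1 ratio and month inheritance", {
  rec <- recovery_experiment(seed = 13, n_animals = 40, days_per_month = 10)
  d <- rec$design
  expect_equal(sum(d$case == 1), sum(d$case == 0))
  expect_true(all(d$prox > 0 & is.finite(d$prox)))
  expect_equal(anyDuplicated(paste(d$animal_id[d$case == 1],
                                   d$month[d$case == 1],
                                   d$winter[d$case == 1],
                                   d$x[d$case == 1])), 0)
  expect_setequal(unique(d$month), "Feb")
})
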