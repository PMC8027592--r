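make_rp <- function(values, cell = 10) {
  structure(list(raster = grid_raster(values, cell_size = cell),
                 month = NA, winter = NA, label = NA,
                 degenerate = FALSE), class = "rp_map")
}

test_that("Kendall tau matches brute-force pair counting and base R", {
  set.seed(20)
  for (rep in 1:40) {
    n <- sample(3:50, 1)
    a <- sample(1:10, n, replace = TRUE)
    b <- if (rep %% 3 == 0) a + sample(-1:1, n, replace = TRUE)
         else sample(1:10, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    kt <- kendall_tau(a, b)
    expect_equal(kt$tau, bf_kendall(a, b), tolerance = 1e-12)
    expect_equal(kt$tau, suppressWarnings(cor(a, b, method = "kendall")),
                 tolerance = 1e-12)
  }
})

test_that("Kendall tau hits the concordance limits and validates input", {
  a <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(kendall_tau(a, a)$tau, 1)
  expect_equal(kendall_tau(a, -a)$tau, -1)
  expect_error(kendall_tau(rep(2, 5), 1:5), "no variation")
  expect_error(kendall_tau(1:4, 1:5), "equal length")
  expect_error(kendall_tau(1, 1), "at least two")
})

test_that("small-sample tau p-values come from exact enumeration", {
  # n = 5, perfect concordance: p = 2/5! under the permutation null
  kt <- kendall_tau(1:5, c(2, 4, 6, 8, 10))
  expect_equal(kt$tau, 1)
  expect_equal(kt$p, 2 / factorial(5))
  # matches base R's exact test when there are no ties
  set.seed(33)
  for (i in 1:5) {
    a <- rnorm(7); b <- rnorm(7)
    ref <- cor.test(a, b, method = "kendall", exact = TRUE)
    kt <- kendall_tau(a, b)
    expect_equal(kt$tau, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(kt$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large-sample tau p-value uses the tie-corrected normal approximation", {
  set.seed(41)
  a <- sample(1:6, 60, replace = TRUE)
  b <- sample(1:6, 60, replace = TRUE)
  kt <- kendall_tau(a, b)
  ref <- suppressWarnings(cor.test(a, b, method = "kendall"))
  expect_equal(kt$p, ref$p.value, tolerance = 1e-8)
})

test_that("AUC equals the exhaustive pairwise comparison", {
  model <- structure(list(beta = c(cc = 0.5, sd = -0.1, prox = 50, inter = 1)),
                     class = "rsf_model")
  set.seed(50)
  for (i in 1:10) {
    d <- data.frame(case = rep(c(1, 0), each = 30),
                    cc = sample(0:1, 60, TRUE), sd = round(runif(60, 0, 50)),
                    prox = round(runif(60, 0.002, 0.02), 3))
    d$inter <- d$sd * d$prox
    scores <- 0.5 * d$cc - 0.1 * d$sd + 50 * d$prox + 1 * d$inter
    expect_equal(roc_auc(model, d), bf_auc(scores, d$case), tolerance = 1e-12)
  }
})

test_that("AUC limits: pure ties give 0.5, perfect separation gives 1", {
  model <- structure(list(beta = c(cc = 1, sd = 0, prox = 0, inter = 0)),
                     class = "rsf_model")
  tied <- data.frame(case = rep(c(1, 0), 10), cc = 1, sd = 0, prox = 1, inter = 0)
  expect_equal(roc_auc(model, tied), 0.5)
  sep <- data.frame(case = rep(c(1, 0), each = 10),
                    cc = rep(c(5, 0), each = 10), sd = 0, prox = 1, inter = 0)
  expect_equal(roc_auc(model, sep), 1)
  expect_error(roc_auc(model, sep[sep$case == 1, ]), "both classes")
})

test_that("use sampled in proportion to Rp yields a perfectly ranked tau", {
  set.seed(60)
  ramp <- matrix(seq(0, 1, length.out = 900), 30, 30)
  rp <- make_rp(ramp)
  cells <- sample.int(900, 5000, replace = TRUE, prob = as.vector(ramp) + 1e-9)
  rows <- (cells - 1) %% 30 + 1; cols <- (cells - 1) %/% 30 + 1
  used <- data.frame(x = (cols - 0.5) * 10, y = (rows - 0.5) * 10)
  v <- area_adjusted_tau(rp, used, n_bins = 10)
  expect_equal(v$tau, 1)
  expect_lt(v$p, 0.001)
  expect_true(all(diff(v$adjusted_freq) > 0))
})

test_that("uniform use over the extent gives near-flat adjusted frequencies", {
  set.seed(61)
  ramp <- matrix(seq(0, 1, length.out = 400), 20, 20)
  rp <- make_rp(ramp)
  sig <- 0
  for (i in 1:40) {
    used <- data.frame(x = runif(400, 0, 200), y = runif(400, 0, 200))
    v <- area_adjusted_tau(rp, used, n_bins = 10)
    expect_true(all(abs(v$adjusted_freq - 1) < 0.6))
    if (v$p <= 0.05) sig <- sig + 1
  }
  expect_lte(sig, 4)  # ~90% of null replicates non-significant
})

test_that("use concentrated in the top bin still ranks positively", {
  ramp <- matrix(seq(0, 1, length.out = 400), 20, 20)
  rp <- make_rp(ramp)
  top <- which(ramp > quantile(ramp, 0.95), arr.ind = TRUE)
  used <- data.frame(x = (top[, 2] - 0.5) * 10, y = (top[, 1] - 0.5) * 10)
  v <- area_adjusted_tau(rp, used, n_bins = 10)
  expect_gt(v$tau, 0)
  expect_equal(sum(v$adjusted_freq[1:9] == 0), 9)
})

test_that("k-fold validation is reproducible and detects real structure", {
  rec <- recovery_experiment(seed = 71, n_animals = 30, days_per_month = 20)
  rep1 <- kfold_validate(rec$design, rec$snow, rec$canopy, rec$dist_fs,
                         rec$dist_floor_m, k = 5, seed = 7,
                         extent = rec$polygon)
  rep2 <- kfold_validate(rec$design, rec$snow, rec$canopy, rec$dist_fs,
                         rec$dist_floor_m, k = 5, seed = 7,
                         extent = rec$polygon)
  expect_identical(rep1, rep2)
  expect_gt(rep1$mean_tau, 0.4)
  expect_true(all(rep1$per_fold_tau > 0))
  expect_equal(length(rep1$per_fold_tau), 5)

  rep3 <- kfold_validate(rec$design, rec$snow, rec$canopy, rec$dist_fs,
                         rec$dist_floor_m, k = 5, seed = 8,
                         extent = rec$polygon)
  expect_false(identical(rep1$per_fold_tau, rep3$per_fold_tau))
})

test_that("temporal validation shares the spatial code path", {
  rec <- recovery_experiment(seed = 73, n_animals = 25, days_per_month = 12)
  rp <- mask_surface(predict_rp(rec$model, rec$snow[[1]], rec$canopy,
                                rec$dist_fs, rec$dist_floor_m), rec$polygon)
  used <- rec$used[in_home_range(rec$polygon, rec$used$x, rec$used$y), ]
  single <- area_adjusted_tau(rp, used, n_bins = 10)
  multi <- validate_map_use(stats::setNames(list(rp), "1999_Feb"), used,
                            n_bins = 10)
  expect_identical(single, multi)
})

test_that("k-fold validation rejects undersized folds", {
  set.seed(74)
  d <- data.frame(case = rep(c(1, 0), each = 45),
                  cc = sample(0:1, 90, TRUE), sd = runif(90, 0, 60),
                  prox = runif(90, 0.001, 0.02),
                  month = "Feb", winter = "1999",
                  x = runif(90, 0, 100), y = runif(90, 0, 100))
  d$inter <- d$sd * d$prox
  snow <- list("1999_Feb" = grid_raster(matrix(30, 10, 10), cell_size = 10))
  canopy <- grid_raster(matrix(rep(0:1, 50), 10, 10), cell_size = 10)
  dfs <- grid_raster(matrix(runif(100, 10, 900), 10, 10), cell_size = 10)
  expect_error(kfold_validate(d, snow, canopy, dfs, 5, k = 5, seed = 1),
               "fewer than 10")
})
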