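test_that("pooled quantile edges follow the interpolated percentile convention", {
  r <- grid_raster(matrix(1:100, 10, 10), cell_size = 10)
  edges <- pooled_quantile_edges(list(r), n_bins = 10)
  expect_equal(edges[1], -Inf)
  expect_equal(edges[11], Inf)
  expect_equal(edges[2:10], seq(10.9, 90.1, by = 9.9), tolerance = 1e-9)
  # each bin receives ~10% of the pooled cells
  bins <- findInterval(1:100, edges, left.open = TRUE, rightmost.closed = TRUE)
  expect_true(all(abs(tabulate(bins, 10) - 10) <= 1))
  flat <- grid_raster(matrix(0.5, 10, 10), cell_size = 10)
  expect_error(pooled_quantile_edges(list(flat)), "distinct")
})

test_that("binning is right-closed and matches a hand lookup", {
  edges <- c(-Inf, 0.2, 0.4, Inf)
  vals <- matrix(c(0.1, 0.2, 0.21, 0.4, 0.41, 0.9, 0, 0.3, 0.39), 3, 3)
  bm <- bin_map(grid_raster(vals, cell_size = 5), edges)
  hand <- matrix(c(1, 1, 2, 2, 3, 3, 1, 2, 2), 3, 3)
  expect_equal(bm$raster$values, hand)
  expect_equal(bm$n_bins, 3)
})

test_that("binning the pooled maps reproduces near-uniform marginals", {
  set.seed(80)
  maps <- lapply(1:3, function(i)
    grid_raster(matrix(runif(2500), 50, 50), cell_size = 10))
  edges <- pooled_quantile_edges(maps, 10)
  pooled_bins <- unlist(lapply(maps, function(m) bin_map(m, edges)$raster$values))
  freq <- tabulate(pooled_bins, 10) / length(pooled_bins)
  expect_true(all(abs(freq - 0.1) < 0.005))
})

test_that("intersection sampling stays inside both polygons and is seeded", {
  maskA <- grid_raster(matrix(0, 20, 20), cell_size = 10)
  maskA$values[1:15, ] <- 1
  maskB <- grid_raster(matrix(0, 20, 20), cell_size = 10)
  maskB$values[10:20, ] <- 1
  hrA <- structure(list(mask = maskA), class = "home_range")
  hrB <- structure(list(mask = maskB), class = "home_range")
  pts <- sample_intersection_points(hrA, hrB, 500, seed = 3)
  idx <- cell_index_at(maskA, pts$x, pts$y)
  expect_true(all(maskA$values[idx] == 1 & maskB$values[idx] == 1))
  expect_identical(pts, sample_intersection_points(hrA, hrB, 500, seed = 3))
  expect_identical(sample_intersection_points(hrA, hrA, 100, seed = 1),
                   {
                     inter <- sample_intersection_points(hrA, hrA, 100, seed = 1)
                     idx2 <- cell_index_at(maskA, inter$x, inter$y)
                     expect_true(all(maskA$values[idx2] == 1))
                     inter
                   })
  maskC <- grid_raster(matrix(0, 20, 20), cell_size = 10)
  maskC$values[18:20, ] <- 1
  hrC <- structure(list(mask = maskC), class = "home_range")
  expect_error(sample_intersection_points(hrA, hrC, 10), "empty")
})

test_that("weighted kappa matches the confusion-matrix oracle exactly", {
  # printed 3-category toy confusion data
  bA <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 2, 1, 3)
  bB <- c(1, 2, 1, 2, 3, 3, 1, 3, 3, 2, 1, 2)
  expect_equal(weighted_kappa(bA, bB, 3), bf_weighted_kappa(bA, bB, 3),
               tolerance = 1e-12)
  set.seed(90)
  for (i in 1:20) {
    n_bins <- sample(c(3, 5, 10), 1)
    a <- sample(seq_len(n_bins), 200, replace = TRUE)
    b <- sample(seq_len(n_bins), 200, replace = TRUE)
    expect_equal(weighted_kappa(a, b, n_bins), bf_weighted_kappa(a, b, n_bins),
                 tolerance = 1e-12)
  }
})

test_that("kappa limits: identity gives 1, chance gives ~0, reversal negative", {
  a <- rep(1:10, each = 20)
  expect_identical(weighted_kappa(a, a, 10), 1)
  set.seed(91)
  u <- sample(1:10, 1000, replace = TRUE)
  v <- sample(1:10, 1000, replace = TRUE)
  expect_lt(abs(weighted_kappa(u, v, 10)), 0.05)
  # reversal: linear disagreement weights give -0.515 for uniform
  # marginals; the -1 reverse-image limit is attained with quadratic ones
  expect_lt(weighted_kappa(a, 11 - a, 10), -0.5)
  expect_equal(weighted_kappa(a, 11 - a, 10, weights = "quadratic"), -1,
               tolerance = 1e-12)
})

test_that("weighted kappa is symmetric and order-invariant", {
  set.seed(92)
  a <- sample(1:5, 300, replace = TRUE)
  b <- pmin(pmax(a + sample(-1:1, 300, replace = TRUE), 1), 5)
  expect_equal(weighted_kappa(a, b, 5), weighted_kappa(b, a, 5))
  perm <- sample(300)
  expect_equal(weighted_kappa(a, b, 5), weighted_kappa(a[perm], b[perm], 5))
  expect_error(weighted_kappa(a, b[1:10], 5), "equal length")
  expect_error(weighted_kappa(c(0, 1), c(1, 2), 5), "outside")
})

test_that("quadratic weights penalise large disagreements more", {
  a <- rep(1:10, each = 30)
  set.seed(93)
  b <- pmin(pmax(a + sample(c(-3, 0, 3), 300, replace = TRUE), 1), 10)
  lin <- weighted_kappa(a, b, 10, weights = "linear")
  quad <- weighted_kappa(a, b, 10, weights = "quadratic")
  expect_false(isTRUE(all.equal(lin, quad)))
})

test_that("category ANOVA reduces to t-test on two balanced groups", {
  recs <- data.frame(
    month = "Feb",
    category = rep(c("intra_h", "intra_c"), each = 6),
    kappa = c(0.41, 0.52, 0.46, 0.39, 0.55, 0.48,
              0.81, 0.77, 0.85, 0.79, 0.88, 0.74))
  out <- compare_categories(recs, "Feb")
  tt <- t.test(kappa ~ category, data = recs, var.equal = TRUE)
  expect_equal(out$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$anova$p, tt$p.value, tolerance = 1e-10)
})

test_that("three-group ANOVA matches hand-computed mean squares", {
  # textbook toy: three groups of four
  k <- c(2, 3, 4, 3, 6, 7, 5, 6, 9, 8, 10, 9)
  recs <- data.frame(month = "Jan",
                     category = rep(c("a", "b", "c"), each = 4), kappa = k)
  grand <- mean(k)
  means <- tapply(k, recs$category, mean)
  ss_b <- 4 * sum((means - grand)^2)
  ss_w <- sum((k - means[recs$category])^2)
  F_hand <- (ss_b / 2) / (ss_w / 9)
  out <- compare_categories(recs, "Jan")
  expect_equal(out$anova$F, F_hand, tolerance = 1e-10)
  expect_equal(out$anova$df_between, 2)
  expect_equal(out$anova$df_within, 9)
  expect_equal(nrow(out$tukey), 3)
  expect_true(all(out$tukey$stars %in% c("", "*", "**", "***")))
})

test_that("identical kappas give F = 0 and no significant pairs", {
  recs <- data.frame(month = "Mar",
                     category = rep(c("intra_h", "intra_c", "inter_decadal"),
                                    each = 3),
                     kappa = 0.5)
  out <- compare_categories(recs, "Mar")
  expect_equal(out$anova$F, 0)
  expect_equal(out$anova$p, 1)
  expect_true(all(out$tukey$stars == ""))
  expect_error(compare_categories(recs[c(1, 4, 7), ], "Mar"), "replication")
})

test_that("subtraction maps are antisymmetric, bounded and scale-checked", {
  set.seed(95)
  edges <- pooled_quantile_edges(
    list(grid_raster(matrix(runif(400), 20, 20), cell_size = 10)), 10)
  a <- bin_map(grid_raster(matrix(runif(400), 20, 20), cell_size = 10), edges)
  b <- bin_map(grid_raster(matrix(runif(400), 20, 20), cell_size = 10), edges)
  self <- subtraction_map(a, a)
  expect_true(all(self$values == 0))
  d_ab <- subtraction_map(a, b)
  d_ba <- subtraction_map(b, a)
  expect_equal(d_ab$values, -d_ba$values)
  expect_true(all(d_ab$values >= -9 & d_ab$values <= 9))
  # extreme case: top bin against bottom bin
  top <- bin_map(grid_raster(matrix(0.999, 2, 2), cell_size = 10), edges)
  bottom <- bin_map(grid_raster(matrix(1e-4, 2, 2), cell_size = 10), edges)
  expect_true(all(subtraction_map(top, bottom)$values == 9))
  other_edges <- edges; other_edges[3] <- other_edges[3] + 0.01
  b2 <- b; b2$edges <- other_edges
  expect_error(subtraction_map(a, b2), "different scales")
})
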