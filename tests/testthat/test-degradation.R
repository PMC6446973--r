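mk100 <- function(v) grid_raster(matrix(v, 4, 4), 100)

test_that("the degradation index sums its components on the masked cells", {
  tch <- mk100(23); lca <- mk100(40); pc <- mk100(90)
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE      # e.g. a wetland cell
  fdi <- compute_fdi(tch, lca, pc, mask)
  expect_true(is.na(fdi$values[1, 1]))
  expect_equal(fdi$values[2, 2], 153)
  zero <- compute_fdi(mk100(0), mk100(0), mk100(0), mask)
  expect_equal(zero$values[3, 3], 0)
  expect_error(compute_fdi(tch, grid_raster(matrix(0, 3, 3), 100), pc, mask),
               "same grid")
})

test_that("the index is strictly increasing in each component", {
  set.seed(31)
  tch <- mk100(runif(16, 5, 30)); lca <- mk100(runif(16, 0, 60))
  pc <- mk100(runif(16, 20, 100))
  mask <- matrix(TRUE, 4, 4)
  base <- compute_fdi(tch, lca, pc, mask)
  for (up in list(list(grid_raster(tch$values + 1, 100), lca, pc),
                  list(tch, grid_raster(lca$values + 1, 100), pc),
                  list(tch, lca, grid_raster(pc$values + 1, 100)))) {
    f2 <- compute_fdi(up[[1]], up[[2]], up[[3]], mask)
    expect_true(all(f2$values > base$values))
  }
})

test_that("supervised thresholds are midpoints between group medians", {
  v <- c(rep(100, 10), rep(150, 10), rep(200, 10), rep(250, 10))
  lab <- rep(c("d", "c", "b", "a"), each = 10)
  thr <- calibrate_fdi_thresholds(v, labels = lab)
  expect_equal(thr, c(125, 175, 225))
  # quantile mode equals brute-force percentiles
  set.seed(32)
  x <- rnorm(500, 150, 40)
  thr2 <- calibrate_fdi_thresholds(x, quantiles = c(0.1, 0.25, 0.5))
  expect_equal(thr2, unname(quantile(x, c(0.1, 0.25, 0.5))))
  # one group only, or unordered medians, are errors
  expect_error(calibrate_fdi_thresholds(v, labels = rep("a", 40)),
               "at least two")
  expect_error(calibrate_fdi_thresholds(c(1, 1, 1, 1),
                                        labels = c("a", "a", "b", "b")),
               "not separable")
})

test_that("classification partitions the masked cells exactly", {
  set.seed(33)
  fdi <- grid_raster(matrix(c(runif(90, 50, 250), rep(NA, 10)), 10, 10), 100)
  thr <- c(110, 160, 210)
  cd <- classify_degradation(fdi, thr)
  cls <- cd$classes$values
  expect_true(all(is.na(cls) == is.na(fdi$values)))
  expect_equal(sum(cd$summary$area_ha), sum(!is.na(fdi$values)) * 1)
  # interval semantics: severe strictly below the first threshold
  expect_true(all(fdi$values[cls == 1L] < 110, na.rm = TRUE))
  expect_true(all(fdi$values[cls == 4L] >= 210, na.rm = TRUE))
  # all cells above the top threshold -> all intact
  hi <- grid_raster(matrix(300, 5, 5), 100)
  cd2 <- classify_degradation(hi, thr)
  expect_true(all(cd2$classes$values == 4L))
  expect_equal(cd2$summary$area_ha[cd2$summary$class == "intact"], 25)
})

test_that("per-class means recover a constructed severity gradient", {
  # four strata of known mean FDI: intact 220, light 170, moderate 120, severe 70
  set.seed(34)
  groups <- rep(1:4, each = 100)
  means <- c(70, 120, 170, 220)[groups]
  v <- matrix(means + runif(400, -10, 10), 20, 20)
  fdi <- grid_raster(v, 100)
  h <- grid_raster(v / 10, 100)
  cd <- classify_degradation(fdi, c(95, 145, 195), height = h)
  s <- cd$summary
  expect_equal(s$mean_height[s$class == "severe"], 7, tolerance = 0.1)
  expect_equal(s$mean_height[s$class == "intact"], 22, tolerance = 0.1)
  # empty mask -> empty summary
  empty <- grid_raster(matrix(NA_real_, 5, 5), 100)
  cd3 <- classify_degradation(empty, c(95, 145, 195))
  expect_true(all(cd3$summary$n_cells == 0))
})

test_that("biomass loss accounting reproduces emission-factor arithmetic", {
  summ <- data.frame(class = c("intact", "degraded"),
                     mean_agb = c(254.79, 171.11),
                     area_ha = c(7171530, 2530874))
  bl <- biomass_loss(summ)
  expect_equal(bl$per_class$emission_factor_Mg_ha, 254.79 - 171.11)
  expect_equal(bl$total_loss_Mg, (254.79 - 171.11) * 2530874)
  # degraded mean equal to intact mean -> zero loss
  same <- data.frame(class = c("intact", "degraded"),
                     mean_agb = c(200, 200), area_ha = c(100, 50))
  expect_equal(biomass_loss(same)$total_loss_Mg, 0)
  expect_error(biomass_loss(data.frame(class = "degraded", mean_agb = 1,
                                       area_ha = 1)), "intact")
})

test_that("loss is invariant to splitting a class at the same weighted mean", {
  joint <- data.frame(class = c("intact", "deg"),
                      mean_agb = c(250, 150), area_ha = c(1000, 600))
  split <- data.frame(class = c("intact", "deg_a", "deg_b"),
                      mean_agb = c(250, 180, 105), area_ha = c(1000, 360, 240))
  # same area-weighted degraded mean: (360*180 + 240*105)/600 = 150
  expect_equal(biomass_loss(split)$total_loss_Mg,
               biomass_loss(joint)$total_loss_Mg)
})
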