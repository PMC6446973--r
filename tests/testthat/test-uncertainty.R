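test_that("pixel error composition satisfies the quadrature identity", {
  g <- function(v) grid_raster(matrix(v, 3, 3), 100)
  model <- list(rmse = 40, mean_agb = 100, cv = NULL)
  # 3-4-5: sigma_rs 30, modeling 40 (absolute), field 0
  st <- compose_pixel_error(g(30), model, g(100), field_rel_error = 0,
                            modeling = "absolute")
  expect_equal(unique(as.vector(st$sigma_total$values)), 50)
  # field term alone: 21.4% of 100 Mg/ha
  st2 <- compose_pixel_error(g(0), list(rmse = 0, mean_agb = 100), g(100))
  expect_equal(unique(as.vector(st2$sigma_field$values)), 21.4)
  expect_equal(unique(as.vector(st2$sigma_total$values)), 21.4)
  # all components zero
  st3 <- compose_pixel_error(g(0), list(rmse = 0, mean_agb = 1), g(0))
  expect_true(all(st3$sigma_total$values == 0))
  # identity holds exactly on random inputs, and total is monotone
  set.seed(41)
  sr <- g(runif(9, 0, 50)); agb <- g(runif(9, 50, 300))
  m2 <- list(rmse = 31.6, mean_agb = 220)
  st4 <- compose_pixel_error(sr, m2, agb)
  expect_equal(st4$sigma_total$values,
               sqrt(st4$sigma_rs$values^2 + st4$sigma_modeling$values^2 +
                      st4$sigma_field$values^2), tolerance = 1e-12)
  st5 <- compose_pixel_error(g(sr$values + 5), m2, agb)
  expect_true(all(st5$sigma_total$values > st4$sigma_total$values))
  expect_error(compose_pixel_error(g(-1), m2, agb), "non-negative")
})

test_that("relative apportionment scales the modeling error with biomass", {
  g <- function(v) grid_raster(matrix(v, 2, 2), 100)
  m <- list(rmse = 30, mean_agb = 200)
  st <- compose_pixel_error(g(0), m, g(c(100, 200, 300, 400)),
                            field_rel_error = 0)
  expect_equal(as.vector(st$sigma_modeling$values), c(100, 200, 300, 400) * 30 / 200)
})

test_that("hand-evaluated class variance cases match the printed formula", {
  co <- cbind(c(0, 100, 200), c(0, 0, 0))
  # m = 2, sigma = (1, 1), rho = 0 -> (1 + 1) / (2 * 1) = 1
  expect_equal(class_variance(c(1, 1), rho_zero_sv, co[1:2, ])$variance, 1)
  # m = 3, sigma = (1, 2, 3), rho = 0 -> 14 / 6
  expect_equal(class_variance(c(1, 2, 3), rho_zero_sv, co)$variance, 14 / 6)
  # rho = 1, equal sigma -> sigma^2 (1/(m-1) + 1)
  s <- rep(2.5, 6)
  co6 <- cbind(seq(0, 500, 100), 0)
  expect_equal(class_variance(s, rho_one_sv, co6)$variance,
               2.5^2 * (1 / 5 + 1), tolerance = 1e-9)
  # classical convention: 1/m^2 normalization
  expect_equal(class_variance(c(1, 1), rho_zero_sv, co[1:2, ],
                              convention = "classical")$variance, 0.5)
  expect_error(class_variance(1, rho_zero_sv, co[1, , drop = FALSE]), "at least 2")
})

test_that("exact and grid evaluations of the class variance agree", {
  set.seed(42)
  sv <- structure(list(c0 = 0.1, c1 = 0.9, range = 300, cutoff = 900,
                       degenerate = FALSE), class = "semivariogram")
  v <- matrix(runif(50 * 50, 5, 40), 50, 50)
  v[sample(2500, 300)] <- NA
  r <- grid_raster(v, 100)
  ex <- class_variance(r, sv, method = "exact")
  gr <- class_variance(r, sv, method = "grid")
  expect_lt(abs(ex$variance - gr$variance) / ex$variance, 0.01)
  # both agree with an independent brute-force double sum on a subgrid
  sub <- grid_raster(v[1:12, 1:12], 100)
  idx <- which(!is.na(sub$values))
  bf <- brute_class_variance(sub$values[idx], gr_coords(sub)[idx, ],
                             function(d) sv_rho(sv, d))
  expect_equal(class_variance(sub, sv)$variance, bf, tolerance = 1e-9)
})

test_that("semivariogram: white noise is degenerate, known range is recovered", {
  set.seed(43)
  wn <- grid_raster(matrix(rnorm(40 * 40), 40, 40), 100)
  sv <- fit_semivariogram(wn, max_lag = 2000)
  expect_true(sv$degenerate || sv$range < 100)
  expect_equal(sv_rho(sv, c(200, 500)), c(0, 0), tolerance = 0.05)
  expect_equal(sv_rho(sv, 0), 1)
  # field generated with a 500-m correlation range: fitted within +/- 50%
  set.seed(44)
  f <- forestdeg:::sim_grf(120, 120, 5)         # 5 cells x 100 m = 500 m
  svf <- fit_semivariogram(grid_raster(f, 100), max_lag = 3000)
  expect_false(svf$degenerate)
  expect_gt(svf$range, 250)
  expect_lt(svf$range, 750)
  # correlation function is non-increasing and clamped to [0, 1]
  d <- seq(0, 5000, 50)
  rho <- sv_rho(svf, d)
  expect_true(all(diff(rho) <= 1e-12))
  expect_true(all(rho >= 0 & rho <= 1))
  expect_equal(rho[d > svf$cutoff], rep(0, sum(d > svf$cutoff)))
})

test_that("empirical semivariance bins equal the brute-force pairwise means", {
  set.seed(45)
  v <- matrix(rnorm(30 * 30, 20, 5), 30, 30)
  r <- grid_raster(v, 100)
  sv <- fit_semivariogram(r, max_lag = 1500, n_bins = 10)
  co <- gr_coords(r)
  z <- as.vector(v)
  dd <- as.vector(dist(co)); gg <- 0.5 * as.vector(dist(z))^2
  keep <- dd > 0 & dd <= 1500
  bin <- factor(cut(dd[keep], seq(0, 1500, length.out = 11),
                    include.lowest = TRUE, labels = FALSE), levels = 1:10)
  expect_equal(unname(sv$empirical$gamma),
               as.vector(tapply(gg[keep], bin, mean)), tolerance = 1e-12)
})

test_that("scene bootstrap: manual two-iteration oracle and near-zero spread", {
  w <- demo_world()
  cfg <- ensemble_config(n_trees = 40, seed = 9)
  boot <- bootstrap_map_uncertainty(w$tch, w$scenes, w$stack, cfg,
                                    fraction = 0.3, iterations = 2, seed = 99)
  # replicate the two scene removals and maps by hand
  set.seed(99)
  n_out <- max(1L, round(0.3 * nrow(w$scenes)))
  splits <- lapply(1:2, function(i) sample.int(nrow(w$scenes), n_out))
  maps <- sapply(1:2, function(it) {
    cfg_it <- cfg; cfg_it$seed <- cfg$seed + it
    fit <- map_height(w$tch, w$scenes[-splits[[it]], ], w$stack, cfg_it)
    as.vector(fit$map$values)
  })
  expect_equal(as.vector(boot$sigma_rs$values), apply(maps, 1, sd),
               tolerance = 1e-9)
  expect_equal(as.vector(boot$mean_map$values), rowMeans(maps),
               tolerance = 1e-9)
  # determinism of the whole scheme under the seed
  boot2 <- bootstrap_map_uncertainty(w$tch, w$scenes, w$stack, cfg,
                                     fraction = 0.3, iterations = 2, seed = 99)
  expect_identical(boot$sigma_rs$values, boot2$sigma_rs$values)
})

test_that("jackknife scene validation pools residuals as stated", {
  w <- demo_world()
  cfg <- ensemble_config(n_trees = 40, seed = 2)
  cv <- leave_one_scene_out(w$tch, w$scenes, w$stack, cfg,
                            class_map = w$truth$class_map)
  expect_equal(nrow(cv$per_scene), nrow(w$scenes))
  # pooled metrics recomputed by hand from the concatenated residuals
  res <- cv$observed - cv$predicted
  expect_equal(unname(cv$pooled[["rmse"]]), sqrt(mean(res^2)), tolerance = 1e-12)
  expect_equal(unname(cv$pooled[["bias"]]), mean(res), tolerance = 1e-12)
  expect_equal(unname(cv$pooled[["r2"]]),
               1 - sum(res^2) / sum((cv$observed - mean(cv$observed))^2),
               tolerance = 1e-12)
  # per-class comparison table covers the observed classes
  expect_true(!is.null(cv$class_comparison))
  expect_true(all(cv$class_comparison$pct_diff_h >= 0))
  # both pooled and mean-over-iterations are reported (they may differ)
  expect_length(cv$mean_over_scenes, 4)
})
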