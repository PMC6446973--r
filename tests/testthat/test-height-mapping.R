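test_that("texture layer equals the brute-force windowed SD everywhere", {
  set.seed(21)
  v <- matrix(runif(40 * 35), 40, 35)
  v[8, 3] <- NA
  tx <- build_texture(grid_raster(v, 25), window = 5)
  for (ij in list(c(1, 1), c(3, 3), c(20, 17), c(40, 35), c(7, 3), c(9, 4))) {
    i <- ij[1]; j <- ij[2]
    expect_equal(tx$values[i, j],
                 if (is.na(v[i, j])) NA_real_ else brute_window_sd(v, i, j),
                 tolerance = 1e-10)
  }
  # constant band has zero texture
  cst <- build_texture(grid_raster(matrix(7, 30, 30), 25))
  expect_true(all(abs(cst$values) < 1e-10))
})

test_that("checkerboard texture equals the analytic interior value", {
  v <- outer(1:20, 1:20, function(i, j) (i + j) %% 2)
  tx <- build_texture(grid_raster(v, 25), window = 5)
  # interior windows hold 12 or 13 ones among 25: population SD
  # sqrt(0.52 * 0.48) = 0.49960
  interior <- tx$values[3:18, 3:18]
  expect_equal(unique(round(as.vector(interior), 6)), 0.49960, tolerance = 1e-6)
  expect_equal(as.vector(interior),
               vapply(3:18, function(j) vapply(3:18, function(i)
                 brute_window_sd(v, i, j), 0), numeric(16)) |> as.vector(),
               tolerance = 1e-12)
})

test_that("the predictor stack holds 14 layers with textures tied to bands", {
  w <- demo_world()
  expect_length(w$stack, 14)
  expect_identical(names(w$stack),
                   c(names(w$bands), paste0(names(w$bands), "_sd")))
  for (r in w$stack) expect_equal(dim(r$values), dim(w$tch$values))
})

test_that("training assembly yields one row per valid scene hectare, deduplicated", {
  tchv <- matrix(runif(10 * 50, 10, 30), 10, 50)
  tch <- grid_raster(tchv, 100)               # 1000 x 5000 m region
  stack <- list(p1 = grid_raster(tchv + 1, 100))
  sc1 <- strip_scene(1)
  tr <- assemble_training(tch, sc1, stack)
  expect_equal(nrow(tr), 500)                 # 500-ha scene -> 500 rows
  # two identical scenes: overlapping cells appear once
  tr2 <- assemble_training(tch, strip_scene(2), stack)
  expect_equal(nrow(tr2), 500)
  # nodata response contributes no rows
  tch_na <- grid_raster(matrix(NA_real_, 10, 50), 100)
  expect_error(assemble_training(tch_na, sc1, stack), "no valid training")
  tchv2 <- tchv; tchv2[, 1:10] <- NA
  tr3 <- assemble_training(grid_raster(tchv2, 100), sc1, stack)
  expect_equal(nrow(tr3), 400)
})

test_that("constant response trains to a constant map", {
  tch <- grid_raster(matrix(15, 10, 50), 100)
  stack <- list(p1 = grid_raster(matrix(runif(500), 10, 50), 100))
  tr <- assemble_training(tch, strip_scene(1), stack)
  fit <- suppressWarnings(          # constant response is intentional here
    train_predict_height(tr, stack, ensemble_config(n_trees = 50)))
  expect_true(all(abs(fit$map$values - 15) < 1e-9))
})

test_that("a noiseless informative predictor is learned to within 1% in-sample", {
  set.seed(22)
  hv <- matrix(runif(20 * 20, 8, 35), 20, 20)
  tch <- grid_raster(hv, 100)
  stack <- list(p1 = grid_raster(hv, 100))     # the predictor IS the response
  sc <- data.frame(scene_id = 1, origin_x = 0, origin_y = 1000, width_m = 2000,
                   length_m = 2000, heading_deg = 90, stratum = 1)
  tr <- assemble_training(tch, sc, stack)
  expect_equal(nrow(tr), 400)
  fit <- train_predict_height(tr, stack,
                              ensemble_config(n_trees = 200, min_leaf = 1))
  rel <- abs(fit$map$values[tr$cell] - tr$tch) / tr$tch
  expect_lt(stats::median(rel), 0.01)
  expect_lt(mean(rel), 0.02)
  # predictions stay inside the convex hull of the response before correction
  expect_gte(min(fit$map$values), min(tr$tch))
  expect_lte(max(fit$map$values), max(tr$tch))
})

test_that("mapping is deterministic under a fixed ensemble seed", {
  w <- demo_world()
  f1 <- map_height(w$tch, w$scenes, w$stack, ensemble_config(n_trees = 60, seed = 3))
  f2 <- map_height(w$tch, w$scenes, w$stack, ensemble_config(n_trees = 60, seed = 3))
  expect_identical(f1$map$values, f2$map$values)
  f3 <- map_height(w$tch, w$scenes, w$stack, ensemble_config(n_trees = 60, seed = 4))
  expect_false(identical(f3$map$values, f1$map$values))
})

test_that("cells with missing predictors are predicted from the valid layers", {
  w <- demo_world()
  cfg <- w$cfg
  cfg$hole_fraction <- 0.15                  # large radar shadows
  bands <- simulate_predictors(w$truth, cfg, seed = 81)
  stack <- build_predictor_stack(bands)
  hole <- is.na(stack$hv$values)
  expect_gt(sum(hole), 0)
  fit <- map_height(w$tch, w$scenes, stack, ensemble_config(n_trees = 60),
                    class_map = w$truth$class_map)
  expect_false(anyNA(fit$map$values[hole]))
})

test_that("bias correction restores unit slope and preserves calibrated means", {
  set.seed(23)
  obs <- runif(300, 5, 35)
  # predictions compressed toward the mean by factor 0.8
  pred <- mean(obs) + 0.8 * (obs - mean(obs)) + rnorm(300, 0, 0.01)
  bc <- bias_correct(pred, pred, obs)
  sl <- coef(lm(bc$map ~ obs))[2]
  expect_equal(unname(sl), 1, tolerance = 0.01)
  expect_equal(mean(bc$map), mean(obs), tolerance = 0.005 * mean(obs))
  # unbiased input passes through unchanged
  bc2 <- bias_correct(obs, obs, obs)
  expect_equal(bc2$map, obs, tolerance = 1e-9)
  expect_equal(bc2$slope, 1, tolerance = 1e-9)
  # degenerate slope skips with a warning
  expect_warning(bc3 <- bias_correct(pred, rep(10, 300) + rnorm(300, 0, 1e-3), obs),
                 "degenerate")
  expect_false(bc3$applied)
})
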