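test_that("cluster geometry: satellites at 250/500 m, missing ones flagged", {
  w <- demo_world()
  ps <- simulate_plots(w$truth, w$scenes, n_clusters = 6, seed = 31)
  expect_equal(nrow(ps$plots), 6 * 9)
  for (k in unique(ps$plots$cluster_id)) {
    cl <- ps$plots[ps$plots$cluster_id == k, ]
    ctr <- cl[cl$role == "center", ]
    expect_equal(nrow(ctr), 1)
    expect_equal(ctr$side_m, 100)
    d <- sqrt((cl$x - ctr$x)^2 + (cl$y - ctr$y)^2)
    expect_setequal(round(d[cl$role != "center"]), c(250, 500))
    expect_true(all(cl$side_m[cl$role != "center"] == 50))
  }
  # flagged missing iff the square leaves the region
  sz <- w$cfg$size
  out_of_region <- with(ps$plots, x - side_m / 2 < 0 | x + side_m / 2 > sz[1] |
                          y - side_m / 2 < 0 | y + side_m / 2 > sz[2])
  expect_identical(ps$plots$missing, out_of_region)
  expect_true(all(is.na(ps$plots$agb[ps$plots$missing])))
})

test_that("plot biomass follows the closed-loop allometry exactly when noiseless", {
  cfg <- landscape_config(
    size = c(3000, 3000), forest_fraction = 1,
    class_fractions = c(terra_firme = 1, wetland = 0, mangrove = 0),
    intact_fraction = 1, plot_agb_sigma = 0, flora_sd_log = 0,
    class_height = list(terra_firme = c(mean = 21.81, sd = 0),
                        wetland = c(mean = 13.5, sd = 0),
                        mangrove = c(mean = 16.5, sd = 0),
                        nonforest = c(mean = 2, sd = 0)))
  tr <- simulate_landscape(cfg, seed = 2)
  sc <- sample_scenes(tr, 2, seed = 3)
  ps <- simulate_plots(tr, sc, n_clusters = 3, seed = 4)
  done <- ps$plots[!ps$plots$missing, ]
  expect_equal(done$tch_true, rep(21.81, nrow(done)))
  expect_equal(done$mean_wd, rep(0.60, nrow(done)))
  # 17.8 * (21.81 * 0.60)^1 = 232.93 Mg/ha
  expect_equal(done$agb, rep(17.8 * 21.81 * 0.60, nrow(done)), tolerance = 1e-12)
})

test_that("identification mix (1,0,0,0) resolves every tree at species level", {
  w <- demo_world()
  cfg <- w$cfg
  cfg$id_mix <- c(species = 1, genus = 0, family = 0, none = 0)
  ps <- simulate_plots(w$truth, w$scenes, n_clusters = 4, seed = 5, config = cfg)
  expect_false(anyNA(ps$trees$species))
  aw <- assign_wood_density(ps$trees, ps$wd_table)
  expect_true(all(aw$trees$wd_level == "species"))
})

test_that("wood density lookup walks species -> genus -> family -> plot mean", {
  tab <- data.frame(name = c("Aa bb", "Aa", "Fabaceae"),
                    rank = c("species", "genus", "family"),
                    wd = c(0.79, 0.65, 0.55))
  trees <- data.frame(plot_id = 1,
                      species = c("Aa bb", "Zz zz", NA, NA),
                      genus = c("Aa", "Aa", NA, NA),
                      family = c("Fabaceae", "Fabaceae", "Fabaceae", NA))
  aw <- assign_wood_density(trees, tab)
  expect_equal(aw$trees$wd, c(0.79, 0.65, 0.55, mean(c(0.79, 0.65, 0.55))))
  expect_equal(aw$trees$wd_level, c("species", "genus", "family", "plot_mean"))
  expect_equal(unname(aw$tally[c("species", "genus", "family", "plot_mean")]),
               rep(1L, 4), ignore_attr = TRUE)
  # class-mean fallback for a plot with no matches at all
  lost <- data.frame(plot_id = 9, species = NA, genus = NA, family = NA)
  aw2 <- assign_wood_density(lost, tab, plot_classes = c(`9` = "terra_firme"),
                             class_wd = c(terra_firme = 0.60))
  expect_equal(aw2$trees$wd, 0.60)
  expect_equal(aw2$trees$wd_level, "class_mean")
  expect_error(assign_wood_density(lost, tab), "no taxonomically matched")
})

test_that("simulated identification levels match the configured mix within 2 pp", {
  w <- demo_world()
  ps <- simulate_plots(w$truth, w$scenes, n_clusters = 10, seed = 6)
  aw <- assign_wood_density(ps$trees, ps$wd_table)
  n <- nrow(aw$trees)
  frac <- table(ps$trees$id_level) / n
  target <- c(species = 0.12, genus = 0.54, family = 0.24, none = 0.10)
  expect_true(all(abs(frac[names(target)] - target) < 0.02))
  # assignment level mirrors the identification level (plot-mean for "none")
  expect_equal(unname(aw$tally[["plot_mean"]]), sum(ps$trees$id_level == "none"))
})

test_that("plot biomass computation converts units and scales linearly", {
  expect_equal(plot_agb(NULL, 100), 0)
  one <- data.frame(dbh_cm = 30, wd = 0.6)
  # one 500-kg stem in 0.25 ha -> 2 Mg/ha
  expect_equal(plot_agb(one, 50, allometry = function(d, w) 500), 2.0)
  trees <- data.frame(dbh_cm = c(12, 25, 40), wd = c(0.5, 0.6, 0.7))
  base <- plot_agb(trees, 100)
  dbl <- plot_agb(trees, 100, allometry = function(d, w) 2 * 0.12 * w * d^2.53)
  expect_equal(dbl, 2 * base)
  expect_error(plot_agb(trees, 70), "unknown plot side")
})

test_that("quarter-plot aggregation averages complete in-scene sets only", {
  mk <- function(set, agb, wd, missing = FALSE, in_scene = TRUE, n = 4)
    data.frame(partner_set = set, agb = agb, mean_wd = wd,
               x = seq_len(n), y = 1, side_m = 50, class = "terra_firme_intact",
               missing = missing, in_scene = in_scene, tch_true = 20)
  full <- mk("a", c(100, 200, 300, 400), c(0.5, 0.6, 0.7, 0.8))
  agg <- aggregate_quarter_plots(full)
  expect_equal(agg$agb, 250)
  expect_equal(agg$mean_wd, 0.65)
  # three members -> excluded
  expect_null(aggregate_quarter_plots(full[1:3, ]))
  # a missing member excludes the whole set
  full$missing[2] <- TRUE
  expect_null(aggregate_quarter_plots(full))
  # out-of-scene member excludes the set
  full$missing[2] <- FALSE; full$in_scene[3] <- FALSE
  expect_null(aggregate_quarter_plots(full))
  # two complete rings -> two aggregated plots from recorded partner sets
  two <- rbind(mk("near", rep(100, 4), 0.6), mk("far", rep(200, 4), 0.6))
  agg2 <- aggregate_quarter_plots(two)
  expect_equal(nrow(agg2), 2)
  expect_setequal(agg2$agb, c(100, 200))
})

test_that("lidar co-location equals the brute-force polygon mean", {
  set.seed(7)
  v <- matrix(runif(400 * 400, 0, 35), 400, 400)
  chm <- grid_raster(v, 1)
  plots <- data.frame(plot_id = 1:2, x = c(150, 320.5), y = c(150, 200.5),
                      side_m = c(100, 50))
  out <- colocate_with_lidar(plots, chm)
  expect_equal(out$tch_lidar[1], mean(v[201:300, 101:200]), tolerance = 1e-12)
  # constant field: exact value regardless of placement
  cst <- colocate_with_lidar(plots, grid_raster(matrix(21.8, 400, 400), 1))
  expect_equal(cst$tch_lidar, c(21.8, 21.8))
  # plot halfway outside is flagged, fully outside is dropped
  edge <- data.frame(plot_id = 1:2, x = c(0, 4000), y = c(200, 200), side_m = 100)
  expect_message(out2 <- colocate_with_lidar(edge, chm), "dropped")
  expect_equal(nrow(out2), 1)
  expect_true(out2$low_coverage)
})

test_that("class mean wood density is the tree-weighted mean and is recoverable", {
  trees <- data.frame(wd = c(0.4, 0.8, 0.6))
  expect_equal(unname(class_mean_wd(trees, c("a", "a", "b"))),
               c(0.6, 0.6), ignore_attr = TRUE)
  # synthetic inventory drawn around (0.60, 0.49, 0.79) recovers class means
  w <- demo_world()
  ps <- simulate_plots(w$truth, w$scenes, n_clusters = 10, seed = 8)
  aw <- assign_wood_density(ps$trees, ps$wd_table)
  cls <- sub("terra_firme_.*", "terra_firme",
             ps$plots$class[match(aw$trees$plot_id, ps$plots$plot_id)])
  got <- class_mean_wd(aw$trees, cls)
  for (cl in names(w$cfg$class_wd)) {
    if (!cl %in% names(got)) next
    n <- sum(cls == cl)
    se <- sd(aw$trees$wd[cls == cl]) / sqrt(n)
    expect_lt(abs(got[[cl]] - w$cfg$class_wd[[cl]]), max(2 * se, 0.04))
  }
  # a class with zero trees is omitted with a warning
  expect_warning(class_mean_wd(data.frame(wd = c(0.5, 0.7)),
                               factor(c("a", "a"), levels = c("a", "b"))),
                 "omitted")
})
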