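#' Synthetic flora and wood-density lookup table
#'
#' Builds a small hierarchical flora (families > genera > species) per forest
#' class, with species wood densities scattered lognormally around the class
#' mean so that the tree-weighted class mean is recoverable. Genus and family
#' entries carry the mean wood density of their members, mimicking a
#' taxonomic wood-density database.
#'
#' @param class_wd named class mean wood densities (g/cm3).
#' @param n_fam families per class; each family holds 2 genera of 2 species.
#' @param sd_log lognormal spread of species wood density around the class mean.
#' @param seed integer seed.
#' @return a list with `species` (data.frame species/genus/family/class/wd)
#'   and `wd_table` (data.frame name/rank/wd usable by
#'   [assign_wood_density()]).
#' @export
synthetic_flora <- function(class_wd = c(terra_firme = 0.60, wetland = 0.49,
                                         mangrove = 0.79),
                            n_fam = 3, sd_log = 0.10, seed = 1) {
  set.seed(seed)
  rows <- NULL
  for (cl in names(class_wd)) {
    for (f in seq_len(n_fam)) {
      fam <- sprintf("%s_fam%02d", cl, f)
      for (g in 1:2) {
        gen <- sprintf("%s_gen%d", fam, g)
        for (s in 1:2) {
          wd <- min(max(class_wd[[cl]] * exp(stats::rnorm(1, 0, sd_log)), 0.15), 1.15)
          rows <- rbind(rows, data.frame(
            species = sprintf("%s_sp%d", gen, s), genus = gen, family = fam,
            class = cl, wd = wd))
        }
      }
    }
  }
  gm <- stats::aggregate(wd ~ genus, rows, mean)
  fm <- stats::aggregate(wd ~ family, rows, mean)
  wd_table <- rbind(
    data.frame(name = rows$species, rank = "species", wd = rows$wd),
    data.frame(name = gm$genus, rank = "genus", wd = gm$wd),
    data.frame(name = fm$family, rank = "family", wd = fm$wd))
  list(species = rows, wd_table = wd_table)
}

# Axis-aligned square plot polygon mean over a 1-m raster; returns mean and
# coverage fraction (pixels inside the raster / plot area).
square_mean <- function(r, cx, cy, side) {
  half <- side / 2
  c1 <- max(1L, ceiling((cx - half - r$xmin) / r$cellsize + 0.5))
  c2 <- min(ncol(r$values), floor((cx + half - r$xmin) / r$cellsize + 0.5))
  r1 <- max(1L, ceiling((r$ymax - (cy + half)) / r$cellsize + 0.5))
  r2 <- min(nrow(r$values), floor((r$ymax - (cy - half)) / r$cellsize + 0.5))
  if (c1 > c2 || r1 > r2) return(c(mean = NA_real_, coverage = 0))
  v <- r$values[r1:r2, c1:c2]
  n_in <- length(v)
  c(mean = mean(v, na.rm = TRUE),
    coverage = sum(!is.na(v)) / (side / r$cellsize)^2)
}

#' Simulate clustered field inventories within lidar scenes
#'
#' Emulates the cluster design of a regional inventory: each cluster has one
#' 1-ha (100 m) permanent plot, snapped to the 1-ha analysis grid, and eight
#' 0.25-ha (50 m) satellite plots at 250 m and 500 m in the four cardinal
#' directions. Satellites falling (partly) outside the region are flagged
#' missing; the recorded `partner_set` groups the four nearest satellites
#' (inner ring, outer ring), fixing the aggregation partners at generation
#' time. Tree lists are drawn with DBH >= 10 cm, species sampled from the
#' synthetic flora of the plot's class, and botanical identification levels
#' drawn from the configured mix. Plot biomass follows the closed-loop
#' stand-in allometry `AGB = a_true (TCH x WD)^b_true` times lognormal noise.
#'
#' @param truth a `landscape_truth`.
#' @param scenes a `scene_footprints` data.frame (>= 1 scene required).
#' @param n_clusters number of plot clusters.
#' @param seed integer seed.
#' @param config the `landscape_config` (defaults to the one inside `truth`);
#'   fields used: `a_true`, `b_true`, `plot_agb_sigma`, `stems_per_ha`,
#'   `id_mix`, `class_wd`.
#' @return a list of class `plot_sample`: `plots` (one row per plot:
#'   `plot_id`, `cluster_id`, `role`, `partner_set`, `x`, `y`, `side_m`,
#'   `class`, `tch_true`, `mean_wd`, `agb`, `missing`), `trees` (one row per
#'   stem: `plot_id`, `x`, `y`, `dbh_cm`, `species`, `genus`, `family`,
#'   `id_level`, `wd_true`), `flora` and `wd_table`.
#' @export
simulate_plots <- function(truth, scenes, n_clusters = 15, seed = 1,
                           config = truth$config) {
  if (nrow(scenes) < 1) stop("at least one scene is required to place plots")
  set.seed(seed)
  flora <- synthetic_flora(config$class_wd, seed = seed,
                           sd_log = if (is.null(config$flora_sd_log)) 0.10 else
                             config$flora_sd_log)
  size <- attr(scenes, "size")
  lev <- attr(truth$class_map, "levels")
  cls30 <- truth$class_map

  pick <- sample(rep_len(seq_len(nrow(scenes)), max(n_clusters, nrow(scenes))),
                 n_clusters)
  # in-region 1-ha cells covered by each scene: cluster centers are drawn
  # from these, which also snaps the permanent plot to the analysis grid
  template <- grid_raster(matrix(0, size[2] / 100, size[1] / 100), 100)
  covered <- scene_cells(scenes, template)$cells
  tco <- gr_coords(template)
  offsets <- rbind(c(0, 0),
                   c(250, 0), c(-250, 0), c(0, 250), c(0, -250),
                   c(500, 0), c(-500, 0), c(0, 500), c(0, -500))
  ring <- c("center", rep("near", 4), rep("far", 4))
  plots <- NULL; trees <- NULL
  pid <- 0L
  for (k in seq_len(n_clusters)) {
    si <- pick[k]
    if (length(covered[[si]]) == 0)
      si <- which(lengths(covered) > 0)[1]
    if (is.na(si)) stop("no scene covers any in-region hectare cell")
    cell <- covered[[si]][sample.int(length(covered[[si]]), 1)]
    cx <- tco[cell, 1]; cy <- tco[cell, 2]
    for (m in seq_len(nrow(offsets))) {
      pid <- pid + 1L
      px <- cx + offsets[m, 1]; py <- cy + offsets[m, 2]
      side <- if (m == 1) 100 else 50
      half <- side / 2
      miss <- px - half < 0 || px + half > size[1] ||
        py - half < 0 || py + half > size[2]
      tchc <- if (miss) c(mean = NA_real_, coverage = 0) else
        square_mean(truth$height_true, px, py, side)
      ccell <- c(
        row = min(max(ceiling((cls30$ymax - py) / 30), 1), nrow(cls30$values)),
        col = min(max(ceiling((px - cls30$xmin) / 30), 1), ncol(cls30$values)))
      cl_code <- cls30$values[ccell["row"], ccell["col"]]
      cl <- lev[cl_code]
      cl_base <- if (cl_code %in% c(1, 2)) "terra_firme" else cl
      pr <- data.frame(
        plot_id = pid, cluster_id = k, role = ring[m],
        partner_set = if (m == 1) NA_character_ else
          sprintf("cluster%02d_%s", k, ring[m]),
        x = px, y = py, side_m = side, class = cl,
        tch_true = unname(tchc["mean"]), mean_wd = NA_real_, agb = NA_real_,
        missing = miss)
      if (!miss && cl_base %in% names(config$class_wd)) {
        n_st <- stats::rpois(1, config$stems_per_ha * (side / 100)^2)
        n_st <- max(n_st, 1L)
        sp_pool <- flora$species[flora$species$class == cl_base, ]
        sp <- sp_pool[sample.int(nrow(sp_pool), n_st, replace = TRUE), ]
        lvl <- sample(names(config$id_mix), n_st, replace = TRUE,
                      prob = config$id_mix)
        tr <- data.frame(
          plot_id = pid,
          x = px + stats::runif(n_st, -half, half),
          y = py + stats::runif(n_st, -half, half),
          dbh_cm = 10 + stats::rexp(n_st, 1 / 12),
          species = ifelse(lvl == "species", sp$species, NA_character_),
          genus = ifelse(lvl %in% c("species", "genus"), sp$genus, NA_character_),
          family = ifelse(lvl != "none", sp$family, NA_character_),
          id_level = lvl, wd_true = sp$wd)
        pr$mean_wd <- mean(tr$wd_true)
        pr$agb <- config$a_true * (pr$tch_true * pr$mean_wd)^config$b_true *
          exp(stats::rnorm(1, 0, config$plot_agb_sigma))
        trees <- rbind(trees, tr)
      }
      plots <- rbind(plots, pr)
    }
  }
  structure(list(plots = plots, trees = trees, flora = flora$species,
                 wd_table = flora$wd_table),
            class = "plot_sample")
}
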