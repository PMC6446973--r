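#' Forest class labels used by the synthetic landscape
#'
#' Integer codes 1..5 in this order label every categorical class raster.
#' @export
FOREST_CLASSES <- c("terra_firme_intact", "terra_firme_degraded",
                    "wetland", "mangrove", "nonforest")

#' Configuration for the synthetic landscape generator
#'
#' Defaults describe a small coastal tropical mosaic: mostly upland (terra
#' firme) forest with wetland and mangrove fringes, a configurable fraction of
#' the upland forest degraded. Class area fractions, wood densities and mean
#' heights follow the regional inventory statistics the pipeline is designed
#' around (terra firme 90.8% of forest at 0.60 g/cm3, wetland 7.8% at 0.49,
#' mangrove 1.4% at 0.79; 63% of terra firme intact).
#'
#' @param size region extent `c(x, y)` in metres; must be a multiple of 300
#'   so the 1-m, 25-m, 30-m and 100-m grids nest.
#' @param height_sim_res resolution (m) at which the correlated height field
#'   is simulated before nearest-neighbour refinement to 1 m.
#' @param forest_fraction fraction of the region that is forest.
#' @param class_fractions named fractions of the *forest* area per class
#'   (terra_firme, wetland, mangrove); must sum to 1.
#' @param intact_fraction fraction of the terra firme area that is intact.
#' @param patch_range correlation range (m) of the class mosaic fields.
#' @param height_corr_range correlation range (m) of the height field.
#' @param class_height named list of `c(mean, sd)` height parameters (m) for
#'   terra_firme (pre-degradation), wetland, mangrove and nonforest.
#' @param class_wd named wood densities (g/cm3) per forest class.
#' @param severity_range range of the uniform degradation severity applied
#'   multiplicatively to heights in degraded cells. The default reproduces a
#'   degraded-class mean height near 16 m given the intact mean.
#' @param gap_height range (m) of replacement heights for felled large-tree
#'   patches inside degraded cells.
#' @param elevation_range range (m asl) of the smooth elevation field.
#' @param sat_height radar cross-pol saturation height (m) for band 6.
#' @param band_noise named per-band Gaussian noise SDs for the 7 predictors.
#' @param hole_fraction fraction of radar-band pixels masked as missing
#'   (emulating topographic shadow).
#' @param a_true,b_true generating coefficients of the plot-level biomass
#'   stand-in allometry `AGB = a (TCH x WD)^b`.
#' @param plot_agb_sigma lognormal sigma of plot biomass noise.
#' @param flora_sd_log lognormal spread of species wood density around the
#'   class mean in the synthetic flora.
#' @param stems_per_ha expected stem density of simulated inventories.
#' @param id_mix fractions of trees identifiable at species / genus / family
#'   level and unidentified; must sum to 1.
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(size = c(6000, 6000),
                             height_sim_res = 5,
                             forest_fraction = 0.92,
                             class_fractions = c(terra_firme = 0.908,
                                                 wetland = 0.078,
                                                 mangrove = 0.014),
                             intact_fraction = 0.63,
                             patch_range = 700,
                             height_corr_range = 150,
                             class_height = list(
                               terra_firme = c(mean = 23.9, sd = 4.1),
                               wetland = c(mean = 13.5, sd = 6.5),
                               mangrove = c(mean = 16.5, sd = 5.5),
                               nonforest = c(mean = 2.0, sd = 1.0)),
                             class_wd = c(terra_firme = 0.60, wetland = 0.49,
                                          mangrove = 0.79),
                             severity_range = c(0.05, 0.60),
                             gap_height = c(2, 8),
                             elevation_range = c(0, 300),
                             sat_height = 25,
                             band_noise = c(red = 0.010, nir = 0.012,
                                            swir1 = 0.010, swir2 = 0.010,
                                            hh = 0.6, hv = 0.7, elev = 5),
                             hole_fraction = 0.02,
                             a_true = 17.8, b_true = 1.0,
                             plot_agb_sigma = 0.23,
                             flora_sd_log = 0.10,
                             stems_per_ha = 550,
                             id_mix = c(species = 0.12, genus = 0.54,
                                        family = 0.24, none = 0.10)) {
  stopifnot(length(size) == 2, all(size > 0),
            abs(sum(class_fractions) - 1) < 1e-8,
            forest_fraction >= 0, forest_fraction <= 1,
            intact_fraction >= 0, intact_fraction <= 1,
            patch_range > 0, height_corr_range > 0,
            all(severity_range >= 0), all(severity_range <= 1),
            abs(sum(id_mix) - 1) < 1e-8)
  if (any(size %% 300 != 0))
    stop("region size must be a multiple of 300 m so that all grids nest")
  if (any(size < 300))
    stop("region too small to host a single 1-ha analysis cell")
  structure(as.list(environment()), class = "landscape_config")
}

# Stationary Gaussian random field on an nr x nc grid with exponential
# autocovariance exp(-d/range) at the given range (in cells), simulated by
# circulant embedding: white noise is convolved (via FFT) with the kernel
# whose spectrum is the square root of the covariance spectrum, so the
# field's covariance — and hence its semivariogram range — matches the
# configured range. Standardized to zero mean / unit variance;
# range_cells <= 0.5 degenerates to white noise.
sim_grf <- function(nr, nc, range_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells > 0.5) {
    dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
    dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
    d <- sqrt(outer(dr^2, dc^2, "+"))
    lam <- Re(stats::fft(exp(-d / range_cells)))
    lam[lam < 0] <- 0
    z <- Re(stats::fft(stats::fft(z) * sqrt(lam), inverse = TRUE)) / (nr * nc)
  }
  (z - mean(z)) / stats::sd(z)
}

# Repeat each matrix cell f x f times (nearest-neighbour refinement).
upsample_factor <- function(m, f) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f), drop = FALSE]
}

# Quantile-based categorical assignment: cells with the lowest `fractions[1]`
# share of field values get code 1, the next band code 2, etc. Realized
# fractions are exact up to cell rounding.
quantile_classes <- function(field, fractions) {
  n <- length(field)
  rk <- rank(field, ties.method = "first")
  cuts <- round(cumsum(fractions) * n)
  out <- matrix(1L + findInterval(rk, cuts + 0.5), nrow(field), ncol(field))
  out
}

#' Simulate a synthetic study landscape with known ground truth
#'
#' Generates a spatially coherent class mosaic (30-m cells), a spatially
#' autocorrelated 1-m canopy height field per class, a wood-density map, a
#' smooth elevation field and a degradation-severity field. Degradation acts
#' multiplicatively on height (`h * (1 - severity)`) and additionally fells
#' surviving large-tree patches (pixels above 27 m are replaced by low gap
#' heights with probability equal to the local severity), so that height,
#' cover and large-tree metrics all respond.
#'
#' All outputs are deterministic functions of `(config, seed)`.
#'
#' @param config a [landscape_config()].
#' @param seed integer random seed.
#' @return a list of class `landscape_truth` with elements `height_true`
#'   (1-m `grid_raster`), `class_map` (30-m categorical), `wd_map` (30-m,
#'   g/cm3), `elevation` (30-m), `degradation_severity` (30-m, 0 on intact
#'   cells), plus the `config` and `seed` used.
#' @export
simulate_landscape <- function(config = landscape_config(), seed = 1) {
  cfg <- config
  set.seed(seed)
  nx30 <- cfg$size[1] / 30; ny30 <- cfg$size[2] / 30
  rng30 <- cfg$patch_range / 30

  # -- class mosaic ----------------------------------------------------------
  f_forest <- sim_grf(ny30, nx30, rng30)
  forest <- quantile_classes(f_forest, c(1 - cfg$forest_fraction,
                                         cfg$forest_fraction)) == 2L
  f_class <- sim_grf(ny30, nx30, rng30)
  # assign forest classes by quantiles of a second field restricted to forest
  cls <- matrix(5L, ny30, nx30)             # 5 = nonforest
  fr <- cfg$class_fractions
  sub <- quantile_classes(matrix(f_class[forest], ncol = 1),
                          c(fr[["mangrove"]], fr[["wetland"]], fr[["terra_firme"]]))
  cls[forest] <- c(4L, 3L, 1L)[sub]         # mangrove, wetland, terra firme
  f_deg <- sim_grf(ny30, nx30, rng30 / 2)
  tf <- cls == 1L
  sub2 <- quantile_classes(matrix(f_deg[tf], ncol = 1),
                           c(1 - cfg$intact_fraction, cfg$intact_fraction))
  cls[tf] <- ifelse(sub2 == 1L, 2L, 1L)     # degraded vs intact

  # -- degradation severity (30 m, smooth, uniform on severity_range) --------
  f_sev <- sim_grf(ny30, nx30, rng30 / 2)
  sev <- matrix(0, ny30, nx30)
  u <- stats::pnorm(f_sev[cls == 2L])
  sev[cls == 2L] <- cfg$severity_range[1] +
    u * diff(cfg$severity_range)

  # -- 1-m height field ------------------------------------------------------
  fh <- cfg$height_sim_res
  nyh <- cfg$size[2] / fh; nxh <- cfg$size[1] / fh
  z <- sim_grf(nyh, nxh, cfg$height_corr_range / fh)
  z1 <- upsample_factor(z, fh)
  ny1 <- cfg$size[2]; nx1 <- cfg$size[1]
  r30 <- rep(seq_len(ny30), each = 30)
  c30 <- rep(seq_len(nx30), each = 30)
  cls1 <- cls[r30, c30, drop = FALSE]
  hp <- cfg$class_height
  mean1 <- matrix(0, ny1, nx1); sd1 <- matrix(0, ny1, nx1)
  grp <- list(`1` = "terra_firme", `2` = "terra_firme", `3` = "wetland",
              `4` = "mangrove", `5` = "nonforest")
  for (k in 1:5) {
    p <- hp[[grp[[as.character(k)]]]]
    idx <- cls1 == k
    mean1[idx] <- p[["mean"]]; sd1[idx] <- p[["sd"]]
  }
  h <- mean1 + sd1 * z1
  h[h < 0] <- 0

  # multiplicative degradation + felling of surviving large-tree patches
  sev1 <- sev[r30, c30, drop = FALSE]
  h <- h * (1 - sev1)
  big <- which(cls1 == 2L & h > 27)
  if (length(big)) {
    felled <- stats::runif(length(big)) < sev1[big]
    h[big[felled]] <- stats::runif(sum(felled), cfg$gap_height[1], cfg$gap_height[2])
  }

  # nonforest guarantee: cells must stay below 30% cover of >5 m pixels
  nf <- which(cls == 5L)
  if (length(nf)) {
    tall30 <- block_sum(((h > 5) & (cls1 == 5L)) + 0, 30L)
    offending <- which(cls == 5L & tall30 / 900 >= 0.30)
    if (length(offending)) {
      bad1 <- matrix(FALSE, ny30, nx30); bad1[offending] <- TRUE
      sel <- bad1[r30, c30, drop = FALSE] & h >= 5
      h[sel] <- 4.9
    }
  }

  # -- ancillary fields ------------------------------------------------------
  elev <- sim_grf(ny30, nx30, 2 * rng30)
  elev <- cfg$elevation_range[1] + (elev - min(elev)) / diff(range(elev)) *
    diff(cfg$elevation_range)
  wd <- matrix(NA_real_, ny30, nx30)
  wd[cls %in% c(1L, 2L)] <- cfg$class_wd[["terra_firme"]]
  wd[cls == 3L] <- cfg$class_wd[["wetland"]]
  wd[cls == 4L] <- cfg$class_wd[["mangrove"]]

  ymax <- cfg$size[2]
  structure(list(
    height_true = grid_raster(h, 1, 0, ymax),
    class_map = grid_raster(cls, 30, 0, ymax, levels = FOREST_CLASSES),
    wd_map = grid_raster(wd, 30, 0, ymax),
    elevation = grid_raster(elev, 30, 0, ymax),
    degradation_severity = grid_raster(sev, 30, 0, ymax),
    config = cfg, seed = seed), class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf("<landscape_truth> %g x %g m, seed %d\n",
              x$config$size[1], x$config$size[2], x$seed))
  tab <- table(factor(x$class_map$values, 1:5, FOREST_CLASSES))
  print(round(100 * tab / sum(tab), 1))
  invisible(x)
}
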