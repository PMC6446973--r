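#' Deterministic signal component of each synthetic predictor band
#'
#' The seven bands emulate an optical + L-band radar + elevation stack at
#' 25-m cells, each a stated monotone function of canopy height (and, for the
#' last band, of terrain elevation):
#'
#' 1. `red`   = 0.30 - 0.005 * min(h, 30)        (reflectance, darkens with canopy)
#' 2. `nir`   = 0.15 + 0.008 * min(h, 30)        (brightens, saturates over closed canopy)
#' 3. `swir1` = 0.35 - 0.006 * min(h, 32)
#' 4. `swir2` = 0.28 - 0.005 * min(h, 32)
#' 5. `hh`    = -12 + 6 * log10(1 + min(h, 35))  (dB, saturates last)
#' 6. `hv`    = -18 + 8 * log10(1 + min(h, sat)) (dB, hard saturation at `sat`)
#' 7. `elev`  = terrain elevation (m)
#'
#' Band 6 is exactly flat above the saturation height, and the optical bands
#' flatten between 30 and 35 m, emulating the progressive loss of predictive
#' value of optical and radar measurements over tall dense canopies.
#'
#' @param band band index 1..7 or name.
#' @param h canopy height (m), any numeric shape.
#' @param elev elevation (m), used by band 7.
#' @param sat_height saturation height (m) for band 6.
#' @return numeric of the same shape as `h`.
#' @export
predictor_signal <- function(band, h, elev = NULL, sat_height = 25) {
  nm <- c("red", "nir", "swir1", "swir2", "hh", "hv", "elev")
  if (is.character(band)) band <- match(band, nm)
  switch(band,
         0.30 - 0.005 * pmin(h, 30),
         0.15 + 0.008 * pmin(h, 30),
         0.35 - 0.006 * pmin(h, 32),
         0.28 - 0.005 * pmin(h, 32),
         -12 + 6 * log10(1 + pmin(h, 35)),
         -18 + 8 * log10(1 + pmin(h, sat_height)),
         elev)
}

#' Simulate the 7-band predictor stack over a synthetic landscape
#'
#' Aggregates the true 1-m height field to 25-m cells, evaluates each band's
#' deterministic signal ([predictor_signal()]), adds independent Gaussian
#' sensor noise per band, and punches spatially coherent missing-data holes
#' into the two radar-like bands (`hh`, `hv`) to emulate topographic shadow.
#'
#' @param truth a `landscape_truth`.
#' @param config the `landscape_config` (defaults to the one inside `truth`);
#'   fields used: `sat_height`, `band_noise`, `hole_fraction`.
#' @param seed integer seed for noise and hole placement.
#' @return a named list of seven 25-m `grid_raster`s
#'   (`red`, `nir`, `swir1`, `swir2`, `hh`, `hv`, `elev`).
#' @export
simulate_predictors <- function(truth, config = truth$config, seed = 1) {
  set.seed(seed)
  h25 <- aggregate_mean(truth$height_true, 25)
  e25 <- resample_nearest(truth$elevation, h25)
  nr <- nrow(h25$values); nc <- ncol(h25$values)
  nm <- names(config$band_noise)
  bands <- vector("list", 7); names(bands) <- nm
  hole <- NULL
  if (config$hole_fraction > 0) {
    f <- sim_grf(nr, nc, config$patch_range / 25 / 2)
    hole <- f >= stats::quantile(f, 1 - config$hole_fraction)
  }
  for (b in 1:7) {
    sig <- predictor_signal(b, h25$values, e25$values, config$sat_height)
    ns <- config$band_noise[[b]]
    v <- sig + (if (ns > 0) matrix(stats::rnorm(nr * nc, 0, ns), nr, nc) else 0)
    if (!is.null(hole) && nm[b] %in% c("hh", "hv")) v[hole] <- NA_real_
    bands[[b]] <- grid_raster(v, 25, h25$xmin, h25$ymax)
  }
  bands
}
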