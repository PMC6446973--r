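#' Build a canopy height model from surface and terrain models
#'
#' The canopy height model (CHM) is the per-pixel difference between the
#' digital surface model and the digital terrain model. Negative differences
#' (terrain noise) are clamped to zero; a pixel is missing whenever either
#' surface is missing.
#'
#' @param dsm,dtm co-registered `grid_raster`s at the same (typically 1-m)
#'   grid, heights in metres.
#' @return a `grid_raster` CHM in metres.
#' @export
build_chm <- function(dsm, dtm) {
  check_aligned(dsm, dtm, "DSM and DTM")
  v <- dsm$values - dtm$values
  v[v < 0] <- 0
  grid_raster(v, dsm$cellsize, dsm$xmin, dsm$ymax)
}

#' Hectare-scale canopy structure metrics
#'
#' Grids a 1-m canopy height model to the 1-ha analysis grid, computing the
#' three structure metrics used throughout the pipeline:
#'
#' * `grid_tch()` — mean top canopy height (TCH, m): the arithmetic mean of
#'   the valid 1-m pixels of each cell;
#' * `compute_pc()` — percent vegetation cover (PC, %): the percentage of
#'   valid pixels strictly taller than `height_threshold` (default 5 m);
#' * `compute_lca()` — large-tree canopy area (LCA, %): the percentage of
#'   valid pixels that belong to canopy patches taller than 27 m whose
#'   4-connected area exceeds 100 m². Patch area is judged globally (patches
#'   may straddle cell borders); pixel counts are attributed per cell.
#'
#' Cells whose fraction of valid 1-m pixels falls below `cover_threshold`
#' are set to missing.
#'
#' @param chm a `grid_raster` canopy height model (m) whose dimensions are
#'   multiples of `cell / chm$cellsize`.
#' @param cell analysis cell edge in metres (default 100, i.e. 1 ha).
#' @param cover_threshold minimum valid-pixel fraction per cell.
#' @param height_threshold cover height cut in metres (strict `>`).
#' @param lca_height height cut defining large trees (strict `>`, m).
#' @param lca_area minimum patch area in m² (strict `>`).
#' @return a `grid_raster` at `cell` resolution (with `valid_fraction`
#'   attribute for `grid_tch`).
#' @export
grid_tch <- function(chm, cell = 100, cover_threshold = 0.5) {
  f <- cell / chm$cellsize
  if (abs(f - round(f)) > 1e-9) stop("cell is not a multiple of the CHM cell size")
  aggregate_mean(chm, round(f), min_valid = cover_threshold)
}

#' @rdname grid_tch
#' @export
compute_pc <- function(chm, cell = 100, cover_threshold = 0.5,
                       height_threshold = 5) {
  f <- round(cell / chm$cellsize)
  valid <- !is.na(chm$values)
  tall <- (chm$values > height_threshold) & valid
  n_tall <- block_sum(tall + 0, f)
  n_valid <- block_sum(valid + 0, f)
  out <- 100 * n_tall / n_valid
  out[n_valid == 0 | n_valid / f^2 < cover_threshold] <- NA_real_
  grid_raster(out, chm$cellsize * f, chm$xmin, chm$ymax)
}

#' @rdname grid_tch
#' @export
compute_lca <- function(chm, cell = 100, cover_threshold = 0.5,
                        lca_height = 27, lca_area = 100) {
  f <- round(cell / chm$cellsize)
  valid <- !is.na(chm$values)
  mask <- (chm$values > lca_height) & valid
  counted <- matrix(FALSE, nrow(mask), ncol(mask))
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask + 0)     # 4-connected component labels
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
    sizes <- tabulate(lab)
    # component area in m^2 = pixel count * pixel area; strict > threshold
    keep <- sizes * chm$cellsize^2 > lca_area
    counted <- lab > 0 & keep[pmax(lab, 1L)]
  }
  n_cnt <- block_sum(counted + 0, f)
  n_valid <- block_sum(valid + 0, f)
  out <- 100 * n_cnt / n_valid
  out[n_valid == 0 | n_valid / f^2 < cover_threshold] <- NA_real_
  grid_raster(out, chm$cellsize * f, chm$xmin, chm$ymax)
}

#' All three hectare metrics at once
#'
#' @inheritParams grid_tch
#' @return a list with `tch`, `pc`, `lca` and `valid_fraction` rasters.
#' @export
hectare_metrics <- function(chm, cell = 100, cover_threshold = 0.5) {
  tch <- grid_tch(chm, cell, cover_threshold)
  list(tch = tch,
       pc = compute_pc(chm, cell, cover_threshold),
       lca = compute_lca(chm, cell, cover_threshold),
       valid_fraction = attr(tch, "valid_fraction"))
}
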