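#' Stratified random placement of lidar flight scenes
#'
#' Places rectangular lidar acquisition footprints by stratified random
#' sampling: scenes are allocated to strata proportionally to stratum area
#' (largest-remainder rounding), and every stratum whose area exceeds
#' `min_stratum_area_ha` receives at least one scene when `n_scenes` allows.
#' Each footprint is 1 km wide, its length is drawn from `lengths` (5, 10 or
#' 20 km, i.e. 500/1000/2000 ha before clipping), and its heading is drawn
#' uniformly from multiples of 45 degrees. Footprints are clipped to the
#' region and placed without mutual overlap by rejection sampling; placement
#' fails with an error if a scene cannot be placed after `max_tries`
#' attempts.
#'
#' @param x a `landscape_truth` (strata default to its forest classes with
#'   nonforest excluded) or a categorical `grid_raster` of strata.
#' @param n_scenes number of footprints to place (0 gives an empty set).
#' @param seed integer seed; placement is deterministic given `(x, seed)`.
#' @param lengths allowed footprint lengths in metres.
#' @param width footprint width in metres (fixed at 1000 by design).
#' @param min_stratum_area_ha strata at least this large are guaranteed a
#'   scene when `n_scenes` permits.
#' @param max_tries rejection-sampling attempts per scene.
#' @return a data.frame of class `scene_footprints` with columns `scene_id`,
#'   `origin_x`, `origin_y` (midpoint of the trailing 1-km edge), `width_m`,
#'   `length_m`, `heading_deg` (clockwise from north) and `stratum`. Region
#'   extent is carried in attributes `size` (m).
#' @export
sample_scenes <- function(x, n_scenes, seed = 1,
                          lengths = c(5000, 10000, 20000), width = 1000,
                          min_stratum_area_ha = 500, max_tries = 500) {
  strata <- if (inherits(x, "landscape_truth")) x$class_map else x
  stopifnot(inherits(strata, "grid_raster"), n_scenes >= 0)
  set.seed(seed)
  size <- c(ncol(strata$values), nrow(strata$values)) * strata$cellsize
  empty <- data.frame(scene_id = integer(), origin_x = numeric(),
                      origin_y = numeric(), width_m = numeric(),
                      length_m = numeric(), heading_deg = numeric(),
                      stratum = integer())
  vals <- strata$values
  if (inherits(x, "landscape_truth"))
    vals[vals == match("nonforest", attr(strata, "levels"))] <- NA
  ids <- sort(unique(vals[!is.na(vals)]))
  if (n_scenes == 0 || length(ids) == 0)
    return(structure(empty, size = size, class = c("scene_footprints", "data.frame")))

  cell_ha <- strata$cellsize^2 / 1e4
  area <- vapply(ids, function(k) sum(vals == k, na.rm = TRUE) * cell_ha, 0)
  # largest-remainder proportional allocation with a floor of 1 for large strata
  quota <- n_scenes * area / sum(area)
  n_s <- floor(quota)
  rem <- n_scenes - sum(n_s)
  if (rem > 0) {
    ord <- order(quota - n_s, decreasing = TRUE)
    n_s[ord[seq_len(rem)]] <- n_s[ord[seq_len(rem)]] + 1
  }
  guaranteed <- which(area >= min_stratum_area_ha)
  while (any(n_s[guaranteed] == 0) && n_scenes >= length(guaranteed)) {
    need <- guaranteed[n_s[guaranteed] == 0][1]
    donor <- which.max(n_s)
    n_s[donor] <- n_s[donor] - 1; n_s[need] <- n_s[need] + 1
  }

  # occupancy grid at 100 m for the non-overlap test
  n100x <- ceiling(size[1] / 100); n100y <- ceiling(size[2] / 100)
  occ <- matrix(FALSE, n100y, n100x)
  cx <- (seq_len(n100x) - 0.5) * 100
  cy <- size[2] - (seq_len(n100y) - 0.5) * 100
  px <- rep(cx, each = n100y); py <- rep(cy, times = n100x)

  co <- gr_coords(strata)
  out <- empty
  sid <- 0L
  for (si in seq_along(ids)) {
    k <- ids[si]
    cells <- which(!is.na(vals) & vals == k)
    for (j in seq_len(n_s[si])) {
      placed <- FALSE
      for (tr in seq_len(max_tries)) {
        anchor <- cells[sample.int(length(cells), 1)]
        ox <- co[anchor, 1] + stats::runif(1, -0.5, 0.5) * strata$cellsize
        oy <- co[anchor, 2] + stats::runif(1, -0.5, 0.5) * strata$cellsize
        hd <- seq(0, 315, by = 45)[sample.int(8, 1)]
        ln <- lengths[sample.int(length(lengths), 1)]
        inside <- points_in_scene(px, py, ox, oy, ln, width, hd)
        if (!any(inside) || any(occ[inside])) next
        occ[inside] <- TRUE
        sid <- sid + 1L
        out <- rbind(out, data.frame(scene_id = sid, origin_x = ox,
                                     origin_y = oy, width_m = width,
                                     length_m = ln, heading_deg = hd,
                                     stratum = as.integer(k)))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place a non-overlapping scene in stratum ", k,
             " after ", max_tries, " attempts")
    }
  }
  rownames(out) <- NULL
  structure(out, size = size, class = c("scene_footprints", "data.frame"))
}

# Membership test for the rotated scene rectangle: u along the heading
# direction in [0, length], v across it in [-width/2, width/2].
points_in_scene <- function(px, py, ox, oy, length_m, width_m, heading_deg) {
  th <- heading_deg * pi / 180
  dx <- sin(th); dy <- cos(th)              # heading clockwise from north
  u <- (px - ox) * dx + (py - oy) * dy
  v <- (px - ox) * dy - (py - oy) * dx
  u >= 0 & u <= length_m & abs(v) <= width_m / 2
}

#' Map scene footprints onto an analysis grid
#'
#' @param scenes a `scene_footprints` data.frame.
#' @param template a `grid_raster` (typically the 100-m TCH map) whose cell
#'   centers are tested for membership.
#' @return a list with `mask` (logical `grid_raster`, TRUE where any scene
#'   covers the cell center) and `cells` (list of integer cell indices in
#'   column-major order, one vector per scene; overlaps are impossible by
#'   construction).
#' @export
scene_cells <- function(scenes, template) {
  co <- gr_coords(template)
  mask <- matrix(FALSE, nrow(template$values), ncol(template$values))
  cells <- vector("list", nrow(scenes))
  for (i in seq_len(nrow(scenes))) {
    s <- scenes[i, ]
    inside <- points_in_scene(co[, 1], co[, 2], s$origin_x, s$origin_y,
                              s$length_m, s$width_m, s$heading_deg)
    cells[[i]] <- which(inside)
    mask[inside] <- TRUE
  }
  list(mask = grid_raster(mask + 0, template$cellsize, template$xmin,
                          template$ymax),
       cells = cells)
}
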