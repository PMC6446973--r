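#' Gridded raster fields
#'
#' `grid_raster` is the carrier for every gridded field in the pipeline:
#' canopy height models, hectare metrics (TCH, PC, LCA), biomass and
#' uncertainty maps, and categorical class mosaics. It is a plain numeric
#' matrix (row 1 = northern edge, column 1 = western edge) together with a
#' square cell size in metres and the coordinate of the top-left corner.
#' Missing data are `NA`. Categorical rasters store integer codes and carry a
#' `levels` attribute naming them.
#'
#' @param values numeric matrix, row-major from the top-left corner.
#' @param cellsize cell edge length in metres (> 0).
#' @param xmin x coordinate of the left (western) raster edge, metres.
#' @param ymax y coordinate of the top (northern) raster edge, metres.
#' @param levels optional character vector of category labels for integer
#'   rasters (e.g. land-cover classes).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, cellsize, xmin = 0, ymax = nrow(values) * cellsize,
                        levels = NULL) {
  stopifnot(is.matrix(values), is.numeric(cellsize), length(cellsize) == 1L,
            cellsize > 0)
  r <- structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax)),
    class = "grid_raster")
  if (!is.null(levels)) attr(r, "levels") <- as.character(levels)
  r
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  lv <- attr(x, "levels")
  cat(sprintf("<grid_raster> %d x %d cells @ %g m (extent %g x %g m)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              ncol(x$values) * x$cellsize, nrow(x$values) * x$cellsize))
  v <- x$values[!is.na(x$values)]
  if (!is.null(lv)) {
    cat("  categorical:", paste(lv, collapse = ", "), "\n")
  } else if (length(v)) {
    cat(sprintf("  range [%.3g, %.3g], %.1f%% valid\n", min(v), max(v),
                100 * length(v) / length(x$values)))
  }
  invisible(x)
}

#' Cell-center coordinates
#'
#' @param r a `grid_raster`.
#' @return `gr_xcoords`/`gr_ycoords`: center coordinates per column/row.
#'   `gr_coords`: a two-column matrix (x, y) for every cell in column-major
#'   matrix order.
#' @export
gr_xcoords <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize

#' @rdname gr_xcoords
#' @export
gr_ycoords <- function(r) r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$cellsize

#' @rdname gr_xcoords
#' @export
gr_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  cbind(x = rep(gr_xcoords(r), each = nr), y = rep(gr_ycoords(r), times = nc))
}

#' Check that two rasters share grid geometry
#'
#' @param a,b `grid_raster` objects.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; stops on mismatch.
#' @export
check_aligned <- function(a, b, what = "rasters") {
  ok <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(a$xmin, b$xmin)) && isTRUE(all.equal(a$ymax, b$ymax))
  if (!ok) stop(what, " are not on the same grid (dimensions, cell size or origin differ)")
  invisible(TRUE)
}

# Block sums over f x f windows via two rowsum passes; NAs contribute 0 and
# are counted separately by the caller.
block_sum <- function(m, f) {
  g1 <- (seq_len(nrow(m)) - 1L) %/% f
  s <- rowsum(m, g1, reorder = TRUE)
  g2 <- (seq_len(ncol(m)) - 1L) %/% f
  out <- t(rowsum(t(s), g2, reorder = TRUE))
  dimnames(out) <- NULL
  out
}

#' Aggregate a raster by block mean
#'
#' Averages `factor` x `factor` blocks of cells, ignoring `NA`s. The raster
#' dimensions must be multiples of `factor`. Cells whose fraction of valid
#' input pixels falls below `min_valid` become `NA`.
#'
#' @param r a `grid_raster`.
#' @param factor integer block edge (e.g. 100 to go from 1-m to 100-m cells).
#' @param min_valid minimum valid-pixel fraction for a block to be reported.
#' @return a `grid_raster` at `cellsize * factor`, with an attribute
#'   `valid_fraction` holding the per-block valid fraction raster.
#' @export
aggregate_mean <- function(r, factor, min_valid = 0) {
  f <- as.integer(factor)
  if (nrow(r$values) %% f || ncol(r$values) %% f)
    stop("raster dimensions are not a multiple of the aggregation factor")
  v <- r$values
  valid <- !is.na(v)
  v[!valid] <- 0
  s <- block_sum(v, f)
  n <- block_sum(valid + 0, f)
  out <- s / n
  out[n == 0] <- NA_real_
  vf <- n / f^2
  out[vf < min_valid] <- NA_real_
  res <- grid_raster(out, r$cellsize * f, r$xmin, r$ymax)
  attr(res, "valid_fraction") <- grid_raster(vf, r$cellsize * f, r$xmin, r$ymax)
  res
}

#' Resample a raster to a new grid by nearest neighbour
#'
#' Looks up, for each cell center of the target grid, the covering cell of the
#' source raster. Used to move the 30-m class mosaic onto 25-m or 100-m
#' analysis grids.
#'
#' @param r source `grid_raster`.
#' @param template `grid_raster` defining the target geometry.
#' @return a `grid_raster` on the template grid (levels attribute preserved).
#' @export
resample_nearest <- function(r, template) {
  xs <- gr_xcoords(template); ys <- gr_ycoords(template)
  col <- pmin(pmax(ceiling((xs - r$xmin) / r$cellsize), 1L), ncol(r$values))
  row <- pmin(pmax(ceiling((r$ymax - ys) / r$cellsize), 1L), nrow(r$values))
  out <- r$values[row, col, drop = FALSE]
  grid_raster(out, template$cellsize, template$xmin, template$ymax,
              levels = attr(r, "levels"))
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text raster interchange (`.asc`): a six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by
#' row-major values from the north-west corner, readable by GDAL and QGIS.
#'
#' @param r a `grid_raster`.
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `write_asc` returns `path` invisibly; `read_asc` a `grid_raster`.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           paste("xllcorner", r$xmin),
           paste("yllcorner", r$ymax - nr * r$cellsize),
           paste("cellsize", r$cellsize),
           paste("NODATA_value", nodata))
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  key <- tolower(hdr$key)
  val <- stats::setNames(hdr$value, key)
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == val[["nodata_value"]]] <- NA_real_
  grid_raster(m, val[["cellsize"]], xmin = val[["xllcorner"]],
              ymax = val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]])
}
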