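#' Forest degradation index
#'
#' The degradation index sums the three hectare-scale structure metrics,
#' `FDI = TCH + LCA + PC` (metres plus two percentages, summed without any
#' unit rescaling; optional min-max normalization of the components is
#' available but off by default). The index is defined on upland (terra
#' firme) forest cells only; all other cells are missing.
#'
#' @param tch,lca,pc aligned 100-m `grid_raster`s.
#' @param mask logical matrix or `grid_raster`: TRUE on terra firme cells.
#' @param normalize min-max normalize each component to `[0, 1]` before
#'   summing (default FALSE).
#' @return a `grid_raster` of FDI values.
#' @export
compute_fdi <- function(tch, lca, pc, mask, normalize = FALSE) {
  check_aligned(tch, lca, "TCH and LCA")
  check_aligned(tch, pc, "TCH and PC")
  mv <- if (inherits(mask, "grid_raster")) mask$values else mask
  stopifnot(identical(dim(mv), dim(tch$values)))
  comp <- list(tch$values, lca$values, pc$values)
  if (normalize)
    comp <- lapply(comp, function(m) {
      rg <- range(m[mv %in% c(TRUE, 1)], na.rm = TRUE)
      if (diff(rg) == 0) m * 0 else (m - rg[1]) / diff(rg)
    })
  v <- comp[[1]] + comp[[2]] + comp[[3]]
  v[!(mv %in% c(TRUE, 1))] <- NA_real_
  grid_raster(v, tch$cellsize, tch$xmin, tch$ymax)
}

#' Degradation class labels, from most to least degraded
#' @export
DEGRADATION_CLASSES <- c("severe", "moderate_to_high", "light", "intact")

#' Calibrate the three FDI class thresholds
#'
#' Supervised mode: given FDI samples labelled by degradation severity group,
#' thresholds are the midpoints between consecutive group medians (groups
#' ordered by median). Quantile mode: thresholds are the stated percentiles
#' of the supplied FDI values. Exactly three thresholds are produced either
#' way (four severity groups, or three quantiles).
#'
#' @param fdi numeric FDI values (vector or `grid_raster`).
#' @param labels optional group labels (same length as `fdi` values); at
#'   least two distinct groups with strictly separable medians.
#' @param quantiles optional numeric vector of three probabilities.
#' @return numeric vector of three strictly ascending thresholds.
#' @export
calibrate_fdi_thresholds <- function(fdi, labels = NULL, quantiles = NULL) {
  v <- if (inherits(fdi, "grid_raster")) as.vector(fdi$values) else fdi
  if (!is.null(labels)) {
    ok <- !is.na(v) & !is.na(labels)
    med <- sort(tapply(v[ok], labels[ok], stats::median))
    if (length(med) < 2)
      stop("supervised threshold calibration needs at least two labelled groups")
    if (any(diff(med) <= 0))
      stop("group medians are not separable in ascending order: ",
           paste(sprintf("%s=%.2f", names(med), med), collapse = ", "))
    thr <- as.numeric(med[-1] + med[-length(med)]) / 2
  } else if (!is.null(quantiles)) {
    stopifnot(length(quantiles) == 3)
    thr <- stats::quantile(v, quantiles, na.rm = TRUE, names = FALSE)
  } else stop("either labels or quantiles must be supplied")
  thr <- unname(thr)
  if (any(diff(thr) <= 0)) stop("calibrated thresholds are not strictly ascending")
  thr
}

#' Classify degradation severity from the FDI
#'
#' Partitions the FDI raster into four classes by three ascending thresholds:
#' `severe` below the first, `moderate_to_high`, `light`, and `intact` at or
#' above the third. Optionally summarizes height and biomass per class.
#'
#' @param fdi a `grid_raster` from [compute_fdi()].
#' @param thresholds three ascending cut values.
#' @param height,agb optional aligned `grid_raster`s summarized per class.
#' @return a list: `classes` (categorical `grid_raster`, levels
#'   [DEGRADATION_CLASSES] coded 1-4) and `summary` (data.frame per class:
#'   `area_ha`, `mean_height`, `sd_height`, `mean_agb`, `sd_agb`, `n_cells`).
#' @export
classify_degradation <- function(fdi, thresholds, height = NULL, agb = NULL) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0))
  v <- fdi$values
  code <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  code[ok] <- findInterval(v[ok], thresholds) + 1L
  cls <- grid_raster(code, fdi$cellsize, fdi$xmin, fdi$ymax,
                     levels = DEGRADATION_CLASSES)
  cell_ha <- fdi$cellsize^2 / 1e4
  summ <- data.frame(class = DEGRADATION_CLASSES,
                     n_cells = NA_integer_, area_ha = NA_real_,
                     mean_height = NA_real_, sd_height = NA_real_,
                     mean_agb = NA_real_, sd_agb = NA_real_)
  for (k in 1:4) {
    idx <- which(code == k)
    summ$n_cells[k] <- length(idx)
    summ$area_ha[k] <- length(idx) * cell_ha
    if (!is.null(height)) {
      summ$mean_height[k] <- mean(height$values[idx], na.rm = TRUE)
      summ$sd_height[k] <- stats::sd(height$values[idx], na.rm = TRUE)
    }
    if (!is.null(agb)) {
      summ$mean_agb[k] <- mean(agb$values[idx], na.rm = TRUE)
      summ$sd_agb[k] <- stats::sd(agb$values[idx], na.rm = TRUE)
    }
  }
  list(classes = cls, summary = summ[nrow(summ):1, ])   # intact first
}

#' Emission factors and regional biomass loss from class summaries
#'
#' For each degraded class, the emission factor is the difference between the
#' intact-class mean biomass density and the class mean (Mg/ha); the percent
#' reduction expresses it relative to the intact mean; and the regional loss
#' is the sum over degraded classes of area times emission factor (Mg).
#' Works directly on any class-summary table carrying mean AGB and area, so
#' published summary tables can be used as inputs.
#'
#' @param summary data.frame with columns `class`, `mean_agb` (Mg/ha) and
#'   `area_ha`.
#' @param intact_label label of the intact reference class.
#' @return a list: `per_class` (data.frame with `emission_factor_Mg_ha`,
#'   `pct_reduction`, `loss_Mg`) and `total_loss_Mg`.
#' @export
biomass_loss <- function(summary, intact_label = "intact") {
  i <- match(intact_label, summary$class)
  if (is.na(i)) stop("summary is missing the intact reference class")
  ref <- summary$mean_agb[i]
  deg <- summary[-i, , drop = FALSE]
  if (nrow(deg) == 0) stop("summary contains no degraded class")
  ef <- ref - deg$mean_agb
  out <- data.frame(class = deg$class,
                    emission_factor_Mg_ha = ef,
                    pct_reduction = 100 * ef / ref,
                    loss_Mg = deg$area_ha * ef)
  list(per_class = out, intact_mean_agb = ref,
       total_loss_Mg = sum(out$loss_Mg))
}
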