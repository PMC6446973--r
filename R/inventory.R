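#' Assign wood density to trees from a taxonomic lookup table
#'
#' Looks each tree up in the wood-density table at species level first, then
#' genus, then family. Trees matched at no rank receive the mean wood density
#' of the matched trees of their plot (`plot_mean` level); a plot with no
#' matched trees at all falls back to the class mean wood density
#' (`class_mean` level) when `class_wd` and the plot's class are available,
#' and is an error otherwise.
#'
#' @param trees data.frame with columns `plot_id`, `species`, `genus`,
#'   `family` (NA where unidentified).
#' @param wd_table data.frame with columns `name`, `rank` (species / genus /
#'   family) and `wd` (g/cm3); (name, rank) pairs must be unique.
#' @param plot_classes optional named vector mapping `plot_id` to class
#'   label, used for the class-mean fallback.
#' @param class_wd optional named class mean wood densities (g/cm3).
#' @return a list: `trees` (input plus `wd` and `wd_level`) and `tally`
#'   (named counts of assignment levels).
#' @export
assign_wood_density <- function(trees, wd_table, plot_classes = NULL,
                                class_wd = NULL) {
  stopifnot(nrow(wd_table) > 0, !anyDuplicated(wd_table[c("name", "rank")]))
  lut <- function(rank) {
    t2 <- wd_table[wd_table$rank == rank, ]
    stats::setNames(t2$wd, t2$name)
  }
  sp <- lut("species"); ge <- lut("genus"); fa <- lut("family")
  wd <- unname(sp[as.character(trees$species)])
  lvl <- ifelse(!is.na(wd), "species", NA_character_)
  i <- is.na(wd)
  wd[i] <- unname(ge[as.character(trees$genus[i])])
  lvl[i & !is.na(wd)] <- "genus"
  i <- is.na(wd)
  wd[i] <- unname(fa[as.character(trees$family[i])])
  lvl[i & !is.na(wd)] <- "family"
  # plot-mean fallback, then class-mean fallback
  for (p in unique(trees$plot_id[is.na(wd)])) {
    sel <- trees$plot_id == p
    matched <- wd[sel][!is.na(wd[sel])]
    if (length(matched)) {
      fillv <- mean(matched); filll <- "plot_mean"
    } else {
      cl <- if (!is.null(plot_classes)) as.character(plot_classes[[as.character(p)]]) else NA
      if (is.na(cl) || is.null(class_wd) || !cl %in% names(class_wd))
        stop("plot ", p, " has no taxonomically matched trees and no class ",
             "wood density to fall back on")
      fillv <- class_wd[[cl]]; filll <- "class_mean"
    }
    wd[sel & is.na(wd)] <- fillv
    lvl[sel & is.na(lvl)] <- filll
  }
  trees$wd <- wd
  trees$wd_level <- lvl
  tally <- table(factor(lvl, c("species", "genus", "family", "plot_mean",
                               "class_mean")))
  list(trees = trees, tally = tally)
}

#' Plot-level aboveground biomass from a tree list
#'
#' Applies a per-stem allometry (dry mass in kg from DBH and wood density),
#' sums over stems and scales by plot area. The default stand-in allometry,
#' `0.12 * wd * dbh^2.53` kg, has the moist-forest pantropical form; any
#' function of `(dbh_cm, wd)` may be substituted.
#'
#' @param trees data.frame with `dbh_cm` and assigned `wd`; may be empty.
#' @param side_m plot side in metres (50 or 100).
#' @param allometry function(dbh_cm, wd) returning kg dry mass per stem.
#' @return plot AGB in Mg/ha.
#' @export
plot_agb <- function(trees, side_m,
                     allometry = function(dbh_cm, wd) 0.12 * wd * dbh_cm^2.53) {
  if (!side_m %in% c(50, 100)) stop("unknown plot side: ", side_m)
  if (is.null(trees) || nrow(trees) == 0) return(0)
  area_ha <- (side_m / 100)^2
  sum(allometry(trees$dbh_cm, trees$wd)) / 1000 / area_ha
}

#' Aggregate quarter-hectare satellite plots into synthetic 1-ha plots
#'
#' Uses the partner sets recorded at generation time (the four nearest
#' 0.25-ha plots of a cluster ring) to build aggregated 1-ha calibration
#' plots: AGB and mean wood density are averaged over the four equal-area
#' members. Partner sets with missing members, or with members outside the
#' lidar scenes, are excluded from calibration (they remain available for
#' wood-density statistics).
#'
#' @param plots data.frame with `partner_set`, `agb`, `mean_wd`, `tch_true`
#'   or `tch_lidar`, `x`, `y`, `missing` and (optionally) `in_scene`.
#' @return a data.frame of aggregated plots (one row per complete set) with
#'   `plot_id`, `agb`, `mean_wd`, centroid coordinates and `side_m = 100`.
#' @export
aggregate_quarter_plots <- function(plots) {
  sets <- unique(plots$partner_set[!is.na(plots$partner_set)])
  out <- NULL
  for (s in sets) {
    mem <- plots[!is.na(plots$partner_set) & plots$partner_set == s, ]
    if (nrow(mem) != 4 || any(mem$missing)) next
    if ("in_scene" %in% names(mem) && !all(mem$in_scene)) next
    row <- data.frame(plot_id = s, agb = mean(mem$agb),
                      mean_wd = mean(mem$mean_wd),
                      x = mean(mem$x), y = mean(mem$y), side_m = 100,
                      class = mem$class[1])
    for (cc in intersect(c("tch_true", "tch_lidar"), names(mem)))
      row[[cc]] <- mean(mem[[cc]])
    out <- rbind(out, row)
  }
  out
}

#' Co-locate plots with the lidar canopy height model
#'
#' Computes each plot's lidar mean top canopy height as the mean of the 1-m
#' CHM pixels inside the (axis-aligned, center-anchored) plot square. Plots
#' with less than `min_coverage` of their area covered by valid CHM pixels
#' are flagged; plots with no overlap at all are dropped with a message.
#'
#' @param plots data.frame with `plot_id`, `x`, `y`, `side_m`.
#' @param chm a 1-m `grid_raster`.
#' @param min_coverage minimum covered-area fraction (default 0.9).
#' @return `plots` with added `tch_lidar` and `chm_coverage` columns and a
#'   logical `low_coverage` flag; no-overlap plots removed.
#' @export
colocate_with_lidar <- function(plots, chm, min_coverage = 0.9) {
  res <- t(vapply(seq_len(nrow(plots)), function(i)
    square_mean(chm, plots$x[i], plots$y[i], plots$side_m[i]),
    c(mean = 0, coverage = 0)))
  plots$tch_lidar <- res[, "mean"]
  plots$chm_coverage <- res[, "coverage"]
  drop <- plots$chm_coverage == 0
  if (any(drop))
    message(sum(drop), " plot(s) without CHM overlap dropped")
  plots <- plots[!drop, , drop = FALSE]
  plots$low_coverage <- plots$chm_coverage < min_coverage
  plots
}

#' Tree-weighted mean wood density per forest class
#'
#' @param trees data.frame with assigned `wd`.
#' @param classes class label per tree (same length as `nrow(trees)`).
#' @return named vector of per-class mean wood density (g/cm3); classes with
#'   zero trees are omitted with a warning.
#' @export
class_mean_wd <- function(trees, classes) {
  expected <- if (is.factor(classes)) levels(classes) else
    unique(as.character(classes[!is.na(classes)]))
  out <- tapply(trees$wd, as.character(classes), mean)
  empt <- setdiff(expected, names(out)[!is.na(out)])
  if (length(empt)) warning("classes without trees omitted: ",
                            paste(empt, collapse = ", "))
  out[!is.na(out)]
}
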