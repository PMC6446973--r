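#' Per-class summary of height and biomass maps
#'
#' Mean, standard deviation, standard error and area per class, for height
#' and biomass. The standard error uses the spatially correlated class
#' variance ([class_variance()]) when per-pixel sigma maps and a
#' semivariogram are supplied, and the classical `sd/sqrt(m)` otherwise.
#'
#' @param height,agb 100-m `grid_raster`s (either may be NULL).
#' @param classes categorical `grid_raster` on the same grid (levels
#'   attribute used for labels).
#' @param sigma_height,sigma_agb optional per-pixel sigma `grid_raster`s.
#' @param sv optional `semivariogram` for the correlated SE.
#' @param convention passed to [class_variance()].
#' @return a data.frame: one row per class with `n_cells`, `area_ha`,
#'   `mean_h`, `sd_h`, `se_h`, `mean_agb`, `sd_agb`, `se_agb`.
#' @export
summarize_classes <- function(height = NULL, agb = NULL, classes,
                              sigma_height = NULL, sigma_agb = NULL,
                              sv = NULL, convention = "sem") {
  lv <- attr(classes, "levels")
  codes <- sort(unique(classes$values[!is.na(classes$values)]))
  cell_ha <- classes$cellsize^2 / 1e4
  one <- function(map, sigma, idx) {
    if (is.null(map)) return(c(NA, NA, NA))
    v <- map$values[idx]
    se <- NA_real_
    if (!is.null(sigma) && !is.null(sv) && length(idx) >= 2) {
      sg <- sigma$values
      keep <- matrix(NA_real_, nrow(sg), ncol(sg))
      keep[idx] <- sg[idx]
      sgr <- grid_raster(keep, sigma$cellsize, sigma$xmin, sigma$ymax)
      se <- tryCatch(class_variance(sgr, sv, convention = convention)$se,
                     error = function(e) NA_real_)
    } else if (sum(!is.na(v)) >= 2) {
      se <- stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    }
    c(mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE), se)
  }
  out <- NULL
  for (k in codes) {
    idx <- which(classes$values == k)
    h <- one(height, sigma_height, idx)
    a <- one(agb, sigma_agb, idx)
    out <- rbind(out, data.frame(
      class = if (!is.null(lv)) lv[k] else as.character(k),
      n_cells = length(idx), area_ha = length(idx) * cell_ha,
      mean_h = h[1], sd_h = h[2], se_h = h[3],
      mean_agb = a[1], sd_agb = a[2], se_agb = a[3]))
  }
  out
}

#' Cross-tabulate two degradation classifications
#'
#' Compares a land-use 2-class map (intact / degraded) with the 4-class
#' index-based classification: counts and row-normalized percentages, plus
#' the 2 x 2 view with the index classes collapsed to intact vs degraded.
#'
#' @param lulc categorical `grid_raster` (2 classes).
#' @param fdi_classes categorical `grid_raster` from
#'   [classify_degradation()].
#' @param intact_labels labels counted as "intact" when collapsing.
#' @return a list: `counts`, `row_pct` (full cross-tab), `counts_2x2`,
#'   `row_pct_2x2`; empty overlap returns empty tables with a warning.
#' @export
confusion_report <- function(lulc, fdi_classes,
                             intact_labels = "intact") {
  check_aligned(lulc, fdi_classes, "classification rasters")
  la <- attr(lulc, "levels"); lb <- attr(fdi_classes, "levels")
  a <- lulc$values; b <- fdi_classes$values
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    warning("classifications do not overlap")
    e <- table(factor(character(), character()), factor(character(), character()))
    return(list(counts = e, row_pct = e, counts_2x2 = e, row_pct_2x2 = e))
  }
  fa <- factor(if (!is.null(la)) la[a[ok]] else a[ok])
  fb <- factor(if (!is.null(lb)) lb[b[ok]] else b[ok])
  counts <- table(lulc = fa, fdi = fb)
  row_pct <- 100 * prop.table(counts, 1)
  fb2 <- factor(ifelse(as.character(fb) %in% intact_labels, "intact", "degraded"),
                c("intact", "degraded"))
  counts2 <- table(lulc = fa, fdi = fb2)
  list(counts = counts, row_pct = row_pct,
       counts_2x2 = counts2, row_pct_2x2 = 100 * prop.table(counts2, 1))
}

#' Pipeline configuration
#'
#' Bundles the per-stage settings of [run_pipeline()]. Iteration counts
#' default to demonstration scale (a 6 x 6 km region, 8 scenes, 20 bootstrap
#' iterations) so a full run stays in the minutes range on one CPU.
#'
#' @param landscape a [landscape_config()].
#' @param n_scenes number of lidar scenes to sample.
#' @param n_clusters number of field plot clusters.
#' @param ensemble an [ensemble_config()].
#' @param model_cv_iterations iterations of the leave-20%-out model CV.
#' @param boot_iterations,boot_fraction scene bootstrap settings.
#' @param run_loso run the leave-one-scene-out validation.
#' @param scene_lengths allowed scene lengths (m).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            n_scenes = 8, n_clusters = 12,
                            ensemble = ensemble_config(),
                            model_cv_iterations = 200,
                            boot_iterations = 20, boot_fraction = 0.3,
                            run_loso = TRUE,
                            scene_lengths = c(5000, 10000, 20000)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-landscape pipeline
#'
#' Executes every stage end to end: landscape simulation, predictor
#' simulation, scene sampling, canopy metrics, plot simulation and
#' inventory processing, height-biomass model fitting and cross-validation,
#' random-forest height mapping with bias correction, biomass conversion
#' through the wood-density map, degradation-index classification with
#' supervised thresholds (labelled by the true severity field), biomass-loss
#' accounting, scene-bootstrap uncertainty, error composition, semivariogram
#' fitting, class summaries with correlated standard errors, the
#' classification cross-tabulation, and (optionally) the leave-one-scene-out
#' validation. Each stage logs one line. The result is a pure function of
#' `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed; stage seeds are derived from it.
#' @param quiet suppress stage logging.
#' @return a list with all stage outputs (see element names).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("[%s] done in %.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  truth <- stage("simulate", simulate_landscape(config$landscape, seed))
  bands <- stage("predictors", simulate_predictors(truth, seed = seed + 1))
  scenes <- stage("scenes", sample_scenes(truth, config$n_scenes, seed = seed + 2,
                                          lengths = config$scene_lengths))
  chm <- truth$height_true
  met <- stage("metrics", hectare_metrics(chm))
  tch <- met$tch

  inv <- stage("inventory", {
    ps <- simulate_plots(truth, scenes, config$n_clusters, seed = seed + 3)
    cls_lookup <- stats::setNames(sub("terra_firme_.*", "terra_firme",
                                      ps$plots$class), ps$plots$plot_id)
    aw <- assign_wood_density(ps$trees, ps$wd_table, plot_classes = cls_lookup,
                              class_wd = config$landscape$class_wd)
    pl <- colocate_with_lidar(ps$plots[!ps$plots$missing, , drop = FALSE], chm)
    insc <- vapply(seq_len(nrow(pl)), function(i) {
      any(vapply(seq_len(nrow(scenes)), function(s)
        points_in_scene(pl$x[i], pl$y[i], scenes$origin_x[s], scenes$origin_y[s],
                        scenes$length_m[s], scenes$width_m[s],
                        scenes$heading_deg[s]), TRUE))
    }, TRUE)
    pl$in_scene <- insc
    agg <- aggregate_quarter_plots(pl)
    centers <- pl[pl$role == "center" & pl$in_scene & !pl$low_coverage, ]
    calib <- rbind(centers[c("plot_id", "agb", "mean_wd", "tch_lidar")],
                   if (!is.null(agg)) agg[c("plot_id", "agb", "mean_wd", "tch_lidar")])
    list(sample = ps, trees = aw$trees, wd_tally = aw$tally, plots = pl,
         aggregated = agg, calibration = calib)
  })

  model <- stage("fit-model", {
    m <- fit_agb_model(inv$calibration)
    m$cv <- cross_validate_agb_model(inv$calibration,
                                     iterations = config$model_cv_iterations,
                                     seed = seed + 4)
    m
  })

  stack <- stage("stack", build_predictor_stack(bands))
  forest_mask100 <- {
    cls100 <- resample_nearest(truth$class_map, tch)
    cls100$values != match("nonforest", FOREST_CLASSES)
  }
  hm <- stage("map-height", map_height(tch, scenes, stack, config$ensemble,
                                       class_map = truth$class_map,
                                       mask = forest_mask100))
  wd100 <- resample_nearest(truth$wd_map, tch)
  agb_map <- stage("map-agb", apply_agb_model(model, hm$map, wd100))

  deg <- stage("degrade", {
    cls100 <- resample_nearest(truth$class_map, tch)
    tf_mask <- matrix(cls100$values %in% match(c("terra_firme_intact",
                                                 "terra_firme_degraded"),
                                               FOREST_CLASSES),
                      nrow(cls100$values), ncol(cls100$values))
    fdi <- compute_fdi(met$tch, met$lca, met$pc, tf_mask)
    sev100 <- resample_nearest(truth$degradation_severity, tch)
    lab <- rep(NA_character_, length(fdi$values))
    tf <- which(tf_mask & !is.na(fdi$values))
    sv <- sev100$values[tf]
    lab_tf <- cut(sv, c(-Inf, 1e-9, 1/3 * max(sv), 2/3 * max(sv), Inf),
                  labels = c("g4_intact", "g3_light", "g2_moderate", "g1_severe"))
    lab[tf] <- as.character(lab_tf)
    thr <- calibrate_fdi_thresholds(as.vector(fdi$values), labels = lab)
    cd <- classify_degradation(fdi, thr, height = hm$map, agb = agb_map)
    loss <- biomass_loss(cd$summary)
    list(fdi = fdi, thresholds = thr, classes = cd$classes,
         summary = cd$summary, loss = loss, tf_mask = tf_mask)
  })

  unc <- stage("uncertainty", {
    boot <- bootstrap_map_uncertainty(tch, scenes, stack, config$ensemble,
                                      fraction = config$boot_fraction,
                                      iterations = config$boot_iterations,
                                      seed = seed + 5,
                                      class_map = truth$class_map,
                                      mask = forest_mask100)
    # delta-method conversion of height sigma to biomass sigma
    dadh <- model$a * model$b *
      (pmax(hm$map$values, 1e-9) * wd100$values)^(model$b - 1) * wd100$values
    sig_rs_agb <- grid_raster(abs(dadh) * boot$sigma_rs$values, tch$cellsize,
                              tch$xmin, tch$ymax)
    stack_err <- compose_pixel_error(sig_rs_agb, model, agb_map)
    sv_fit <- fit_semivariogram(stack_err$sigma_total, seed = seed + 6)
    list(boot = boot, sigma_rs_agb = sig_rs_agb, stack = stack_err,
         variogram = sv_fit)
  })

  rep <- stage("report", {
    cls100 <- resample_nearest(truth$class_map, tch)
    lulc <- summarize_classes(hm$map, agb_map, cls100,
                              sigma_height = unc$boot$sigma_rs,
                              sigma_agb = unc$stack$sigma_total,
                              sv = unc$variogram)
    fdi_sum <- summarize_classes(hm$map, agb_map, deg$classes,
                                 sigma_height = unc$boot$sigma_rs,
                                 sigma_agb = unc$stack$sigma_total,
                                 sv = unc$variogram)
    # 2-class land-use view: intact vs degraded terra firme
    code2 <- matrix(NA_integer_, nrow(cls100$values), ncol(cls100$values))
    code2[cls100$values == match("terra_firme_intact", FOREST_CLASSES)] <- 1L
    code2[cls100$values == match("terra_firme_degraded", FOREST_CLASSES)] <- 2L
    lulc2 <- grid_raster(code2, tch$cellsize, tch$xmin, tch$ymax,
                         levels = c("intact", "degraded"))
    conf <- confusion_report(lulc2, deg$classes)
    list(lulc_summary = lulc, fdi_summary = fdi_sum, confusion = conf,
         lulc2 = lulc2)
  })

  loso <- if (config$run_loso)
    stage("validate", leave_one_scene_out(tch, scenes, stack, config$ensemble,
                                          class_map = truth$class_map,
                                          model = model, wd = truth$wd_map))
  else NULL

  list(truth = truth, bands = bands, scenes = scenes, metrics = met,
       inventory = inv, model = model, stack = stack, height = hm,
       agb = agb_map, degradation = deg, uncertainty = unc,
       reports = rep, loso = loso, seed = seed, config = config)
}
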