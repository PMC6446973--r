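#' Local standard-deviation texture of a predictor band
#'
#' Sliding-window population standard deviation over a `window` x `window`
#' pixel neighbourhood at the band's native resolution, computed with
#' integral images. Edge pixels use the valid clamped sub-window; missing
#' pixels are excluded from their neighbours' windows and stay missing
#' themselves.
#'
#' @param band a `grid_raster` at native (25-30 m) resolution.
#' @param window odd window edge in pixels (default 5).
#' @return a `grid_raster` of local SD on the same grid.
#' @export
build_texture <- function(band, window = 5) {
  v <- band$values
  nr <- nrow(v); nc <- ncol(v)
  half <- (window - 1) %/% 2
  valid <- !is.na(v)
  v0 <- ifelse(valid, v, 0)
  isum <- function(m) {
    m <- apply(m, 2, cumsum)
    m <- t(apply(m, 1, cumsum))
    rbind(0, cbind(0, m))      # (nr+1) x (nc+1), zero-padded
  }
  I1 <- isum(v0); I2 <- isum(v0^2); In <- isum(valid + 0)
  i1 <- pmax(seq_len(nr) - half, 1L); i2 <- pmin(seq_len(nr) + half, nr)
  j1 <- pmax(seq_len(nc) - half, 1L); j2 <- pmin(seq_len(nc) + half, nc)
  win <- function(I) I[i2 + 1L, j2 + 1L, drop = FALSE] -
    I[i1, j2 + 1L, drop = FALSE] - I[i2 + 1L, j1, drop = FALSE] +
    I[i1, j1, drop = FALSE]
  n <- win(In); s1 <- win(I1); s2 <- win(I2)
  mu <- s1 / n
  va <- pmax(s2 / n - mu^2, 0)
  out <- sqrt(va)
  out[n == 0 | !valid] <- NA_real_
  grid_raster(out, band$cellsize, band$xmin, band$ymax)
}

#' Assemble the 14-layer predictor stack at the analysis grid
#'
#' Aggregates each native-resolution band to the 100-m grid by block mean and
#' appends its local-SD texture layer ([build_texture()], computed at native
#' resolution and then aggregated), giving the 7 + 7 = 14 predictor layers
#' used by the height regressor.
#'
#' @param bands named list of native-resolution `grid_raster`s.
#' @param cell analysis cell edge in metres (default 100).
#' @param window texture window in native pixels.
#' @return a named list of 14 `grid_raster`s: the bands followed by
#'   `<band>_sd` texture layers.
#' @export
build_predictor_stack <- function(bands, cell = 100, window = 5) {
  stack <- list()
  for (nm in names(bands)) {
    f <- round(cell / bands[[nm]]$cellsize)
    stack[[nm]] <- aggregate_mean(bands[[nm]], f)
  }
  for (nm in names(bands)) {
    f <- round(cell / bands[[nm]]$cellsize)
    stack[[paste0(nm, "_sd")]] <- aggregate_mean(build_texture(bands[[nm]], window), f)
  }
  stack
}

#' Training table for the height regressor
#'
#' One row per valid 1-ha cell whose center falls inside any lidar scene
#' footprint: the lidar TCH response plus the 14 predictor values. Cells
#' covered by several scenes appear once. Rows with missing response are
#' dropped; missing predictor values are retained (imputed downstream).
#'
#' @param tch 100-m `grid_raster` of lidar TCH (response).
#' @param scenes a `scene_footprints` data.frame.
#' @param stack predictor stack from [build_predictor_stack()].
#' @return data.frame with `cell` (column-major index into the 100-m grid),
#'   `x`, `y`, one column per predictor, and `tch`.
#' @export
assemble_training <- function(tch, scenes, stack) {
  sc <- scene_cells(scenes, tch)
  cells <- sort(unique(unlist(sc$cells)))
  keep <- cells[!is.na(tch$values[cells])]
  if (length(keep) == 0) stop("no valid training cells inside the lidar scenes")
  co <- gr_coords(tch)
  out <- data.frame(cell = keep, x = co[keep, 1], y = co[keep, 2])
  for (nm in names(stack)) out[[nm]] <- stack[[nm]]$values[keep]
  out$tch <- tch$values[keep]
  out
}

#' Ensemble regressor configuration
#'
#' Defaults follow the tuned random-forest settings for this problem: 500
#' trees, one candidate variable per split, minimum leaf size 13.
#'
#' @param n_trees,mtry,min_leaf random-forest hyperparameters.
#' @param seed integer seed for bagging and feature selection.
#' @return a list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 500, mtry = 1, min_leaf = 13, seed = 1) {
  stopifnot(n_trees >= 1, mtry >= 1, min_leaf >= 1)
  structure(list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 seed = seed), class = "ensemble_config")
}

# Median imputation of missing predictors, optionally conditioned on a class
# raster: per-class training medians, global median as last resort.
impute_predictors <- function(x, cls = NULL, medians = NULL) {
  if (is.null(medians)) {
    medians <- list(global = vapply(x, function(c) stats::median(c, na.rm = TRUE), 0))
    if (!is.null(cls)) {
      medians$by_class <- lapply(split(seq_len(nrow(x)), cls), function(i)
        vapply(x[i, , drop = FALSE], function(c) stats::median(c, na.rm = TRUE), 0))
    }
  }
  for (j in seq_along(x)) {
    miss <- which(is.na(x[[j]]))
    if (!length(miss)) next
    if (!is.null(cls) && !is.null(medians$by_class)) {
      fill <- vapply(as.character(cls[miss]), function(k) {
        m <- medians$by_class[[k]]
        if (is.null(m) || is.na(m[j])) medians$global[j] else m[j]
      }, 0)
    } else fill <- medians$global[j]
    x[[j]][miss] <- fill
  }
  list(x = x, medians = medians)
}

#' Train the height regressor and predict the wall-to-wall map
#'
#' Fits a random forest (bagged regression trees) of lidar TCH on the 14
#' predictor layers and predicts every cell of the stack. Cells with some
#' predictors missing are predicted from the remaining layers through
#' class-conditional median imputation (the class map, when supplied,
#' conditions the imputation); cells whose predictors are all missing become
#' missing with a logged count. Returns the per-cell ensemble mean and the
#' between-tree spread, plus out-of-bag predictions at the training cells for
#' bias correction.
#'
#' @param training table from [assemble_training()].
#' @param stack predictor stack (list of 100-m `grid_raster`s).
#' @param config an [ensemble_config()].
#' @param class_map optional categorical `grid_raster` (any resolution) used
#'   to condition imputation.
#' @param mask optional logical matrix/`grid_raster`; cells outside are not
#'   predicted.
#' @return a list of class `height_map_fit`: `map` and `spread`
#'   (`grid_raster`s), `rf` (the randomForest object), `oob_pred`, `obs`,
#'   `training`, `medians`.
#' @export
train_predict_height <- function(training, stack, config = ensemble_config(),
                                 class_map = NULL, mask = NULL) {
  pred_names <- names(stack)
  xtr <- training[pred_names]
  template <- stack[[1]]
  cls_cells <- NULL
  if (!is.null(class_map)) {
    cls_r <- resample_nearest(class_map, template)
    cls_cells <- as.vector(cls_r$values)
  }
  imp <- impute_predictors(xtr, if (is.null(cls_cells)) NULL else
    cls_cells[training$cell])
  all_na <- rowSums(!is.na(xtr)) == 0
  keep <- !all_na
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = imp$x[keep, , drop = FALSE], y = training$tch[keep],
    ntree = config$n_trees, mtry = config$mtry, nodesize = config$min_leaf,
    keep.forest = TRUE)

  # full-map prediction
  newx <- data.frame(lapply(stack, function(r) as.vector(r$values)))
  n_missing_all <- 0L
  sel <- rep(TRUE, nrow(newx))
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "grid_raster")) mask$values else mask
    sel <- as.vector(mv) %in% c(TRUE, 1)
  }
  all_na_cell <- rowSums(!is.na(newx)) == 0
  n_missing_all <- sum(all_na_cell & sel)
  sel <- sel & !all_na_cell
  newimp <- impute_predictors(newx[sel, , drop = FALSE],
                              if (is.null(cls_cells)) NULL else cls_cells[sel],
                              medians = imp$medians)
  pr <- stats::predict(rf, newimp$x, predict.all = TRUE)
  mp <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  sp <- mp
  mp[sel] <- pr$aggregate
  sp[sel] <- apply(pr$individual, 1, stats::sd)
  if (n_missing_all > 0)
    message(n_missing_all, " cell(s) had no valid predictors and stay missing")
  structure(list(
    map = grid_raster(mp, template$cellsize, template$xmin, template$ymax),
    spread = grid_raster(sp, template$cellsize, template$xmin, template$ymax),
    rf = rf, oob_pred = unname(rf$predicted), obs = training$tch[keep],
    training = training, medians = imp$medians),
    class = "height_map_fit")
}

#' Linear bias correction of ensemble predictions
#'
#' Tree ensembles compress predictions toward the training mean (dilution
#' bias). The correction regresses out-of-bag predictions on the
#' observations, `oob = b0 + b1 * obs`, and inverts that line on the map:
#' `corrected = (pred - b0) / b1`, restoring unit slope against the
#' observations. A degenerate slope (|b1| < 0.1) skips the correction with a
#' warning.
#'
#' @param map `grid_raster` (or numeric vector) of predictions.
#' @param oob_pred out-of-bag (or held-out) predictions at training cells.
#' @param obs observed responses at the same cells.
#' @return a list: `map` (corrected, same class as input), `intercept`,
#'   `slope`, `applied`.
#' @export
bias_correct <- function(map, oob_pred, obs) {
  cf <- stats::coef(stats::lm(oob_pred ~ obs))
  b0 <- unname(cf[1]); b1 <- unname(cf[2])
  applied <- TRUE
  if (!is.finite(b1) || abs(b1) < 0.1) {
    warning("degenerate calibration slope (", format(b1), "); correction skipped")
    applied <- FALSE
  } else if (inherits(map, "grid_raster")) {
    map$values <- (map$values - b0) / b1
  } else {
    map <- (map - b0) / b1
  }
  list(map = map, intercept = b0, slope = b1, applied = applied)
}

#' Full height-mapping step
#'
#' Convenience wrapper: assemble training, fit and predict
#' ([train_predict_height()]), then bias-correct ([bias_correct()]).
#'
#' @inheritParams train_predict_height
#' @inheritParams assemble_training
#' @param correct_bias apply the linear recalibration (default TRUE).
#' @return a `height_map_fit` with corrected `map`, the uncorrected map in
#'   `map_raw`, and the `bias` correction parameters.
#' @export
map_height <- function(tch, scenes, stack, config = ensemble_config(),
                       class_map = NULL, mask = NULL, correct_bias = TRUE) {
  training <- assemble_training(tch, scenes, stack)
  fit <- train_predict_height(training, stack, config, class_map, mask)
  fit$map_raw <- fit$map
  if (correct_bias) {
    bc <- bias_correct(fit$map, fit$oob_pred, fit$obs)
    fit$map <- bc$map
    fit$bias <- bc[c("intercept", "slope", "applied")]
  }
  fit
}
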