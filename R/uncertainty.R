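#' Agreement metrics between observed and predicted values
#'
#' @param obs,pred numeric vectors (NA pairs dropped).
#' @return named vector: `r2` (1 - SSres/SStot), `rmse`, `bias`
#'   (mean(observed - predicted)) and `n`.
#' @export
cv_metrics <- function(obs, pred) {
  ok <- !is.na(obs) & !is.na(pred)
  obs <- obs[ok]; pred <- pred[ok]
  sst <- sum((obs - mean(obs))^2)
  c(r2 = if (sst > 0) 1 - sum((obs - pred)^2) / sst else NA_real_,
    rmse = sqrt(mean((obs - pred)^2)), bias = mean(obs - pred),
    n = length(obs))
}

#' Bootstrap map uncertainty by scene-level cross-validation
#'
#' Scenes (not cells) are the resampling unit, preventing spatial leakage: at
#' each iteration a random `fraction` of the lidar scenes is withheld, the
#' height regressor retrained on the rest, and the full map re-predicted.
#' The per-pixel standard deviation across the iteration maps is the
#' remote-sensing error term sigma_RS; metrics on the withheld scene cells
#' give the leave-30%-out cross-validation report.
#'
#' @inheritParams map_height
#' @param fraction fraction of scenes withheld per iteration (default 0.3).
#' @param iterations number of iterations (default 100).
#' @param seed integer seed.
#' @return a list: `sigma_rs` and `mean_map` (`grid_raster`s), `report`
#'   (pooled + per-iteration metrics on withheld cells), `iterations_used`.
#' @export
bootstrap_map_uncertainty <- function(tch, scenes, stack,
                                      config = ensemble_config(),
                                      fraction = 0.3, iterations = 100,
                                      seed = 1, class_map = NULL, mask = NULL,
                                      correct_bias = TRUE) {
  n_sc <- nrow(scenes)
  if (n_sc < 4) stop("at least 4 scenes are required")
  n_out <- max(1L, round(fraction * n_sc))
  if (n_out >= n_sc) stop("fraction leaves no training scenes")
  set.seed(seed)
  splits <- lapply(seq_len(iterations), function(i) sample.int(n_sc, n_out))
  sc <- scene_cells(scenes, tch)
  ncell <- length(tch$values)
  maps <- matrix(NA_real_, ncell, iterations)
  per <- matrix(NA_real_, iterations, 4,
                dimnames = list(NULL, c("r2", "rmse", "bias", "n")))
  obs_all <- pred_all <- numeric(0)
  used <- 0L
  for (it in seq_len(iterations)) {
    out_sc <- splits[[it]]
    cfg_it <- config
    cfg_it$seed <- config$seed + it
    fit <- tryCatch(
      map_height(tch, scenes[-out_sc, , drop = FALSE], stack, cfg_it,
                 class_map = class_map, mask = mask,
                 correct_bias = correct_bias),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("iteration ", it, " skipped (no training data)")
      next
    }
    used <- used + 1L
    maps[, it] <- as.vector(fit$map$values)
    test_cells <- unique(unlist(sc$cells[out_sc]))
    test_cells <- test_cells[!is.na(tch$values[test_cells])]
    o <- tch$values[test_cells]; p <- fit$map$values[test_cells]
    per[it, ] <- cv_metrics(o, p)
    obs_all <- c(obs_all, o); pred_all <- c(pred_all, p)
  }
  dims <- dim(tch$values)
  sig <- matrix(apply(maps, 1, stats::sd, na.rm = TRUE), dims[1], dims[2])
  mn <- matrix(rowMeans(maps, na.rm = TRUE), dims[1], dims[2])
  list(sigma_rs = grid_raster(sig, tch$cellsize, tch$xmin, tch$ymax),
       mean_map = grid_raster(mn, tch$cellsize, tch$xmin, tch$ymax),
       report = list(scheme = "leave30pct",
                     pooled = cv_metrics(obs_all, pred_all),
                     per_iteration = as.data.frame(per),
                     mean_over_iterations = colMeans(per, na.rm = TRUE)),
       iterations_used = used)
}

#' Compose per-pixel biomass uncertainty
#'
#' Combines the three independent error terms in quadrature,
#' `sigma_total^2 = sigma_RS^2 + sigma_modeling^2 + sigma_field^2`:
#' the mapping error from scene bootstrapping (sigma_RS), the height-biomass
#' model error apportioned per pixel, and the field measurement + allometry
#' error (default 21.4% of pixel biomass). The model error is apportioned
#' relatively by default — `(model CV RMSE / mean calibration AGB) * AGB(u)`
#' — because biomass-model residuals scale with biomass; an absolute mode
#' applies the RMSE uniformly. Height maps use sigma_RS alone.
#'
#' @param sigma_rs `grid_raster` of mapping error (Mg/ha).
#' @param model an `agb_model`; its cross-validation RMSE (element
#'   `cv$rmse`, falling back to the resubstitution `rmse`) and mean
#'   calibration AGB drive the modeling term.
#' @param agb `grid_raster` of predicted biomass (Mg/ha).
#' @param field_rel_error relative field/allometry error (default 0.214).
#' @param modeling `"relative"` (default) or `"absolute"` apportionment.
#' @return a list of class `uncertainty_stack` with `sigma_rs`,
#'   `sigma_modeling`, `sigma_field`, `sigma_total` `grid_raster`s.
#' @export
compose_pixel_error <- function(sigma_rs, model, agb,
                                field_rel_error = 0.214,
                                modeling = c("relative", "absolute")) {
  modeling <- match.arg(modeling)
  check_aligned(sigma_rs, agb, "sigma_RS and AGB maps")
  if (any(sigma_rs$values < 0, na.rm = TRUE) || any(agb$values < 0, na.rm = TRUE) ||
      field_rel_error < 0)
    stop("error components must be non-negative")
  rmse <- if (!is.null(model$cv)) model$cv$rmse else model$rmse
  s_field <- field_rel_error * agb$values
  s_model <- if (modeling == "relative")
    (rmse / model$mean_agb) * agb$values
  else (agb$values * 0) + rmse
  s_tot <- sqrt(sigma_rs$values^2 + s_model^2 + s_field^2)
  g <- function(v) grid_raster(v, agb$cellsize, agb$xmin, agb$ymax)
  structure(list(sigma_rs = sigma_rs, sigma_modeling = g(s_model),
                 sigma_field = g(s_field), sigma_total = g(s_tot)),
            class = "uncertainty_stack")
}

#' Fit an exponential semivariogram to a gridded field
#'
#' Computes the empirical semivariance by distance bin (all cell pairs when
#' the field has at most `max_cells` valid cells, otherwise a seeded random
#' subsample) and fits the exponential model
#' `gamma(d) = c0 + c1 (1 - exp(-d / range))` by least squares. The derived
#' correlation function is `rho(d) = 1 - gamma(d) / (c0 + c1)` clamped to
#' `[0, 1]`, equal to 1 at d = 0 and 0 beyond the practical range
#' `cutoff = 3 * range`. A flat variogram is flagged degenerate, with
#' `rho(d > 0) = 0`.
#'
#' @param r a `grid_raster` (e.g. residuals or a sigma map).
#' @param max_lag largest pair distance used (default: half the maximum
#'   pair distance).
#' @param n_bins number of distance bins.
#' @param max_cells pairwise computation is exact up to this many cells.
#' @param seed seed for the subsample when needed.
#' @return an object of class `semivariogram`: `c0`, `c1`, `range`,
#'   `cutoff`, `degenerate` and the `empirical` bin table.
#' @export
fit_semivariogram <- function(r, max_lag = NULL, n_bins = 15,
                              max_cells = 4000, seed = 1) {
  idx <- which(!is.na(r$values))
  if (length(idx) < 100) stop("at least 100 valid cells are required")
  if (length(idx) > max_cells) {
    set.seed(seed)
    idx <- sort(sample(idx, max_cells))
  }
  co <- gr_coords(r)[idx, , drop = FALSE]
  z <- r$values[idx]
  dd <- as.vector(stats::dist(co))
  gg <- 0.5 * as.vector(stats::dist(z))^2
  if (is.null(max_lag)) max_lag <- max(dd) / 2
  keep <- dd <= max_lag & dd > 0
  dd <- dd[keep]; gg <- gg[keep]
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- factor(cut(dd, breaks, include.lowest = TRUE, labels = FALSE),
                levels = seq_len(n_bins))
  emp <- data.frame(
    dist = as.vector(tapply(dd, bin, mean)),
    gamma = as.vector(tapply(gg, bin, mean)),
    n = as.vector(table(bin)))
  emp <- emp[!is.na(emp$gamma), , drop = FALSE]
  s2 <- stats::var(z)
  obj <- function(p) {
    g <- p[1] + p[2] * (1 - exp(-emp$dist / p[3]))
    sum((g - emp$gamma)^2)
  }
  fit <- stats::optim(c(c0 = emp$gamma[1] / 2, c1 = max(s2 - emp$gamma[1] / 2, 1e-8),
                        range = max_lag / 6), obj, method = "L-BFGS-B",
                      lower = c(0, 0, max_lag / 1e4))
  c0 <- fit$par[[1]]; c1 <- fit$par[[2]]; rg <- fit$par[[3]]
  # flat variogram: spatial structure explains almost none of the sill, or
  # the fitted range collapses to the lower bound
  degenerate <- c0 + c1 == 0 || c1 <= 0.05 * (c0 + c1) ||
    rg <= max_lag / 1e4 * 1.01
  structure(list(c0 = c0, c1 = c1, range = rg, cutoff = 3 * rg,
                 degenerate = degenerate, empirical = emp),
            class = "semivariogram")
}

#' Spatial correlation implied by a fitted semivariogram
#'
#' @param sv a `semivariogram`.
#' @param d numeric distances (m).
#' @return correlations in `[0, 1]`; 1 at d = 0, 0 beyond the cutoff (and at
#'   all positive distances for a degenerate fit).
#' @export
sv_rho <- function(sv, d) {
  out <- numeric(length(d))
  out[d <= 0] <- 1
  pos <- d > 0
  if (any(pos) && !sv$degenerate) {
    g <- sv$c0 + sv$c1 * (1 - exp(-d[pos] / sv$range))
    rho <- 1 - g / (sv$c0 + sv$c1)
    rho[d[pos] > sv$cutoff] <- 0
    out[pos] <- pmin(pmax(rho, 0), 1)
  }
  out
}

#' @export
print.semivariogram <- function(x, ...) {
  cat(sprintf("<semivariogram> nugget %.4g, partial sill %.4g, range %.1f m%s\n",
              x$c0, x$c1, x$range, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Class-level variance of a mean with spatially correlated errors
#'
#' Integrates per-pixel uncertainties over a class, accounting for spatial
#' correlation of the errors:
#' `sigma2(class) = 1/(m(m-1)) * (sum_i sigma_i^2 + 2 sum_{i<j} rho(d_ij) sigma_i sigma_j)`
#' with `rho` from the fitted semivariogram. The `1/(m(m-1))` normalization,
#' which mirrors the squared standard error of a mean, is the default
#' (`convention = "sem"`); the classical `1/m^2` variance of a correlated
#' mean is available as `convention = "classical"`.
#'
#' For up to `exact_limit` pixels the double sum is evaluated exactly from
#' pairwise distances. Larger gridded inputs use an exact-on-grid kernel
#' evaluation: `rho` depends only on the displacement between cells and
#' vanishes beyond the cutoff, so the cross sum is accumulated over the
#' finite set of displacement offsets.
#'
#' @param sigma per-pixel uncertainties: a `grid_raster` (NA outside the
#'   class) or a numeric vector with `coords`.
#' @param sv a `semivariogram` (or any object usable by [sv_rho()]).
#' @param coords two-column matrix of pixel coordinates when `sigma` is a
#'   vector.
#' @param convention `"sem"` (1/(m(m-1))) or `"classical"` (1/m^2)
#'   normalization.
#' @param method `"auto"`, `"exact"` or `"grid"`.
#' @param exact_limit pixel count up to which `"auto"` stays exact.
#' @return a list: `variance`, `se`, `m`, `method`, `convention`.
#' @export
class_variance <- function(sigma, sv, coords = NULL,
                           convention = c("sem", "classical"),
                           method = c("auto", "exact", "grid"),
                           exact_limit = 5000) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  is_raster <- inherits(sigma, "grid_raster")
  if (is_raster) {
    idx <- which(!is.na(sigma$values))
    s <- sigma$values[idx]
  } else {
    stopifnot(!is.null(coords))
    ok <- !is.na(sigma)
    s <- sigma[ok]; coords <- coords[ok, , drop = FALSE]
  }
  m <- length(s)
  if (m < 2) stop("class variance needs at least 2 pixels")
  if (any(s < 0)) stop("sigma values must be non-negative")
  if (method == "auto")
    method <- if (m <= exact_limit || !is_raster) "exact" else "grid"
  if (method == "exact") {
    co <- if (is_raster) gr_coords(sigma)[idx, , drop = FALSE] else coords
    cross <- 0
    for (i in seq_len(m - 1)) {
      j <- (i + 1):m
      d <- sqrt((co[j, 1] - co[i, 1])^2 + (co[j, 2] - co[i, 2])^2)
      cross <- cross + s[i] * sum(sv_rho(sv, d) * s[j])
    }
  } else {
    if (!is_raster) stop("grid method needs a grid_raster input")
    cs <- sigma$cellsize
    R <- max(1L, ceiling(sv$cutoff / cs))
    S <- sigma$values
    S[is.na(S)] <- 0
    nr <- nrow(S); nc <- ncol(S)
    cross2 <- 0
    for (dr in -R:R) for (dc in -R:R) {
      if (dr == 0 && dc == 0) next
      d <- cs * sqrt(dr^2 + dc^2)
      if (d > sv$cutoff) next
      rho <- sv_rho(sv, d)
      if (rho <= 0) next
      r1 <- max(1, 1 + dr):min(nr, nr + dr)
      r2 <- r1 - dr
      c1 <- max(1, 1 + dc):min(nc, nc + dc)
      c2 <- c1 - dc
      cross2 <- cross2 + rho * sum(S[r1, c1] * S[r2, c2])
    }
    cross <- cross2 / 2
  }
  tot <- sum(s^2) + 2 * cross
  v <- if (convention == "sem") tot / (m * (m - 1)) else tot / m^2
  list(variance = v, se = sqrt(v), m = m, method = method,
       convention = convention)
}

#' Leave-one-scene-out (jackknife) map validation
#'
#' Withholds each lidar scene in turn, retrains the height regressor on the
#' remaining scenes and predicts the withheld scene's cells. Reports
#' per-scene metrics, pooled metrics over all held-out cells, and — when a
#' biomass model and wood-density map are supplied — a per-class comparison
#' of mean height and biomass between the lidar "truth" and the independent
#' prediction, with percent differences.
#'
#' @inheritParams map_height
#' @param model optional `agb_model` for the biomass comparison.
#' @param wd optional 100-m wood-density `grid_raster`.
#' @return a list of class `cv_report`: `scheme`, `per_scene`, `pooled`,
#'   `mean_over_scenes`, and optionally `class_comparison`.
#' @export
leave_one_scene_out <- function(tch, scenes, stack, config = ensemble_config(),
                                class_map = NULL, model = NULL, wd = NULL,
                                correct_bias = TRUE) {
  n_sc <- nrow(scenes)
  if (n_sc < 2) stop("at least 2 scenes are required")
  sc <- scene_cells(scenes, tch)
  per <- matrix(NA_real_, n_sc, 4, dimnames = list(NULL, c("r2", "rmse", "bias", "n")))
  obs_all <- pred_all <- numeric(0)
  cls_all <- character(0)
  cls_r <- if (!is.null(class_map)) resample_nearest(class_map, tch) else NULL
  for (i in seq_len(n_sc)) {
    test_cells <- sc$cells[[i]]
    test_cells <- test_cells[!is.na(tch$values[test_cells])]
    if (!length(test_cells)) next
    msk <- matrix(FALSE, nrow(tch$values), ncol(tch$values))
    msk[test_cells] <- TRUE
    cfg_it <- config
    cfg_it$seed <- config$seed + i
    fit <- map_height(tch, scenes[-i, , drop = FALSE], stack, cfg_it,
                      class_map = class_map, mask = msk,
                      correct_bias = correct_bias)
    o <- tch$values[test_cells]; p <- fit$map$values[test_cells]
    per[i, ] <- cv_metrics(o, p)
    obs_all <- c(obs_all, o); pred_all <- c(pred_all, p)
    if (!is.null(cls_r)) {
      lv <- attr(cls_r, "levels")
      cls_all <- c(cls_all, lv[cls_r$values[test_cells]])
    }
  }
  out <- list(scheme = "leave_one_scene_out",
              per_scene = as.data.frame(per),
              pooled = cv_metrics(obs_all, pred_all),
              mean_over_scenes = colMeans(per, na.rm = TRUE),
              observed = obs_all, predicted = pred_all)
  if (length(cls_all)) {
    conv <- function(h, w) if (is.null(model)) h else model$a * (h * w)^model$b
    wd_all <- if (!is.null(wd)) {
      wr <- resample_nearest(wd, tch)
      # recover per-test-cell wd in the same concatenation order
      unlist(lapply(seq_len(n_sc), function(i) {
        tc <- sc$cells[[i]]; tc <- tc[!is.na(tch$values[tc])]
        wr$values[tc]
      }))
    } else NULL
    tab <- NULL
    for (cl in sort(unique(cls_all))) {
      j <- cls_all == cl
      row <- data.frame(class = cl, n = sum(j),
                        mean_obs_h = mean(obs_all[j]),
                        mean_pred_h = mean(pred_all[j]),
                        pct_diff_h = 100 * abs(mean(obs_all[j]) - mean(pred_all[j])) /
                          mean(obs_all[j]))
      if (!is.null(model) && !is.null(wd_all)) {
        ao <- conv(obs_all[j], wd_all[j]); ap <- conv(pred_all[j], wd_all[j])
        row$mean_obs_agb <- mean(ao); row$mean_pred_agb <- mean(ap)
        row$pct_diff_agb <- 100 * abs(mean(ao) - mean(ap)) / mean(ao)
      }
      tab <- rbind(tab, row)
    }
    out$class_comparison <- tab
  }
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$scheme, "\n  pooled: ")
  cat(sprintf("R2 = %.3f, RMSE = %.3f, bias = %.3f (n = %d)\n",
              x$pooled[["r2"]], x$pooled[["rmse"]], x$pooled[["bias"]],
              as.integer(x$pooled[["n"]])))
  invisible(x)
}
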