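#' Fit the wood-density aware power-law height-biomass model
#'
#' Fits `AGB = a (TCH x WD)^b` to 1-ha calibration plots by nonlinear least
#' squares on the untransformed biomass scale (squared-AGB-residual loss),
#' with fixed start values `a = 10, b = 1` so the fit is deterministic given
#' the data.
#'
#' @param plots data.frame with columns `tch_lidar` (m), `mean_wd` (g/cm3)
#'   and `agb` (Mg/ha); at least 5 rows, all positive heights and densities.
#' @param start named start values for the optimizer.
#' @return an object of class `agb_model`: coefficients `a`, `b`,
#'   resubstitution diagnostics `r2`, `rmse`, `bias` (Mg/ha), `n_plots`, the
#'   mean calibration AGB (used for relative error apportionment) and the
#'   underlying `nls` fit.
#' @export
fit_agb_model <- function(plots, start = c(a = 10, b = 1)) {
  stopifnot(all(c("tch_lidar", "mean_wd", "agb") %in% names(plots)))
  d <- plots[stats::complete.cases(plots[c("tch_lidar", "mean_wd", "agb")]), ]
  if (nrow(d) < 5) stop("at least 5 complete calibration plots are required")
  if (any(d$tch_lidar <= 0) || any(d$mean_wd <= 0))
    stop("calibration plots must have positive TCH and wood density")
  x <- d$tch_lidar * d$mean_wd
  y <- d$agb
  fit <- tryCatch(
    stats::nls(y ~ a * x^b, start = as.list(start),
               control = stats::nls.control(maxiter = 500, scaleOffset = 1)),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e)))
  pred <- stats::fitted(fit)
  res <- y - pred
  structure(list(
    a = unname(stats::coef(fit)[["a"]]), b = unname(stats::coef(fit)[["b"]]),
    r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(res^2)), bias = mean(res),
    n_plots = nrow(d), mean_agb = mean(y), fit = fit),
    class = "agb_model")
}

#' @export
print.agb_model <- function(x, ...) {
  cat(sprintf("AGB = %.3f (TCH x WD)^%.3f   [n = %d plots]\n", x$a, x$b,
              x$n_plots))
  cat(sprintf("  resubstitution R2 = %.3f, RMSE = %.2f Mg/ha, bias = %.2f\n",
              x$r2, x$rmse, x$bias))
  if (!is.null(x$cv))
    cat(sprintf("  CV (leave-%d%%-out, %d it.): R2 = %.3f, RMSE = %.2f, bias = %.2f\n",
                round(100 * x$cv$holdout), x$cv$iterations, x$cv$r2,
                x$cv$rmse, x$cv$bias))
  invisible(x)
}

#' Leave-k%-out cross-validation of the height-biomass model
#'
#' At each iteration a random `holdout` fraction of the plots (sampling
#' without replacement, plots as units) is withheld, the model refitted on
#' the remainder, and the held-out plots predicted. Pooled diagnostics are
#' computed on the concatenated held-out residuals over all iterations
#' (`bias` is mean(observed - predicted)); per-iteration diagnostics are also
#' returned.
#'
#' @inheritParams fit_agb_model
#' @param holdout fraction of plots withheld per iteration (default 0.2).
#' @param iterations number of random splits (default 1000).
#' @param seed integer seed making the split sequence reproducible.
#' @return a list: pooled `r2`, `rmse`, `bias`, `holdout`, `iterations` and a
#'   data.frame `per_iteration`.
#' @export
cross_validate_agb_model <- function(plots, holdout = 0.2, iterations = 1000,
                                     seed = 1, start = c(a = 10, b = 1)) {
  d <- plots[stats::complete.cases(plots[c("tch_lidar", "mean_wd", "agb")]), ]
  n <- nrow(d)
  if (n < 10) stop("at least 10 plots are required for cross-validation")
  n_out <- max(1L, round(holdout * n))
  if (n_out >= n) stop("holdout fraction leaves no training plots")
  set.seed(seed)
  obs_all <- pred_all <- numeric(0)
  per <- matrix(NA_real_, iterations, 3,
                dimnames = list(NULL, c("r2", "rmse", "bias")))
  for (it in seq_len(iterations)) {
    test <- sample.int(n, n_out)
    m <- fit_agb_model(d[-test, , drop = FALSE], start = start)
    p <- m$a * (d$tch_lidar[test] * d$mean_wd[test])^m$b
    o <- d$agb[test]
    obs_all <- c(obs_all, o); pred_all <- c(pred_all, p)
    sst <- sum((o - mean(o))^2)
    per[it, ] <- c(if (sst > 0) 1 - sum((o - p)^2) / sst else NA,
                   sqrt(mean((o - p)^2)), mean(o - p))
  }
  res <- obs_all - pred_all
  sst <- sum((obs_all - mean(obs_all))^2)
  list(r2 = if (sst > 0) 1 - sum(res^2) / sst else 1,
       rmse = sqrt(mean(res^2)), bias = mean(res),
       holdout = holdout, iterations = iterations,
       per_iteration = as.data.frame(per))
}

#' Convert a height map to biomass through the fitted model
#'
#' Applies `AGB = a (H x WD)^b` per pixel. Height and wood-density maps must
#' share the 100-m grid; missing data in either propagates.
#'
#' @param model an `agb_model` (or any list with elements `a` and `b`).
#' @param height a `grid_raster` of canopy height (m).
#' @param wd a `grid_raster` of wood density (g/cm3) on the same grid.
#' @return a `grid_raster` of AGB (Mg/ha).
#' @export
apply_agb_model <- function(model, height, wd) {
  check_aligned(height, wd, "height and wood-density maps")
  h <- pmax(height$values, 0)
  grid_raster(model$a * (h * wd$values)^model$b, height$cellsize,
              height$xmin, height$ymax)
}
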