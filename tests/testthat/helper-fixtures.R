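# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small (3 x 3 km) default-parameter landscape with scenes, plots, predictor
# stack and hectare metrics - the workhorse fixture for integration-level
# tests.
demo_world <- function() {
  if (!is.null(.fixtures$world)) return(.fixtures$world)
  cfg <- landscape_config(size = c(3000, 3000))
  truth <- simulate_landscape(cfg, seed = 11)
  scenes <- sample_scenes(truth, 5, seed = 12)
  bands <- simulate_predictors(truth, seed = 13)
  met <- hectare_metrics(truth$height_true)
  .fixtures$world <- list(
    cfg = cfg, truth = truth, scenes = scenes, bands = bands,
    stack = build_predictor_stack(bands), metrics = met, tch = met$tch)
  .fixtures$world
}

# A single scene covering a 1000 x 5000 m strip exactly (for training-table
# geometry tests), as a bare footprint table.
strip_scene <- function(n = 1) {
  data.frame(scene_id = seq_len(n), origin_x = 0, origin_y = 500,
             width_m = 1000, length_m = 5000, heading_deg = 90,
             stratum = 1L)[rep(1, n), ]
}

# Brute-force oracles ---------------------------------------------------------

# Block mean over f x f windows by explicit looping.
brute_block_mean <- function(v, f) {
  nr <- nrow(v) / f; nc <- ncol(v) / f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- mean(v[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)],
                      na.rm = TRUE)
  out
}

# Windowed population SD at pixel (i, j) with edge-clamped window.
brute_window_sd <- function(v, i, j, w = 5) {
  h <- (w - 1) %/% 2
  sub <- v[max(1, i - h):min(nrow(v), i + h),
           max(1, j - h):min(ncol(v), j + h)]
  sub <- sub[!is.na(sub)]
  sqrt(mean(sub^2) - mean(sub)^2)
}

# Correlated class variance by direct double sum.
brute_class_variance <- function(s, coords, rho_fun, sem = TRUE) {
  m <- length(s)
  tot <- sum(s^2)
  cross <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    cross <- cross + rho_fun(d) * s[i] * s[j]
  }
  (tot + 2 * cross) / if (sem) (m * (m - 1)) else m^2
}

# Semivariogram objects with fixed correlation for hand-checkable cases.
rho_zero_sv <- structure(list(c0 = 1, c1 = 0, range = 1, cutoff = 3,
                              degenerate = TRUE), class = "semivariogram")
rho_one_sv <- structure(list(c0 = 0, c1 = 1, range = 1e12, cutoff = Inf,
                             degenerate = FALSE), class = "semivariogram")

# Calibration plots for model tests: exact power-law data, no noise.
noiseless_plots <- function(n = 30, a = 17.8, b = 1.0, seed = 42) {
  set.seed(seed)
  tch <- runif(n, 8, 35)
  wd <- sample(c(0.60, 0.49, 0.79), n, replace = TRUE)
  data.frame(tch_lidar = tch, mean_wd = wd, agb = a * (tch * wd)^b)
}
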