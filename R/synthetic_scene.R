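#' Synthetic scene configuration
#'
#' Parameters for the desk-scale scene generators. The generators emulate
#' the statistical structure the pipeline assumes in its production inputs:
#' per-pixel seasonal sinusoidal greenness, cloud-gap patterns with
#' per-scene cloud cover, smooth coarse temperature/radiation fields with
#' seasonal cycles, and spatially autocorrelated grassland masks. Identical
#' configurations (including the seed) give bit-identical outputs.
#'
#' @param grid_width,grid_height pixel counts (>= 1).
#' @param pixel_size metres, default 30.
#' @param origin upper-left corner coordinates.
#' @param years inclusive year range, e.g. `c(2020, 2021)`.
#' @param seed integer RNG seed.
#' @param cloud_gap_fraction fraction in \[0,1\] of pixels flagged missing
#'   per pre-composite scene.
#' @param noise_sd reflectance noise standard deviation.
#' @param seasonal_amplitude peak-to-mean NIR seasonal amplitude (reflectance
#'   units); 0 gives a season-free scene.
#' @param hemisphere `"north"` (greenness peaks in period 4, Jul--Aug) or
#'   `"south"` (peaks in period 1).
#' @param lst_mean,lst_amplitude seasonal mean and amplitude of land surface
#'   temperature, degrees C.
#' @param par_mean,par_amplitude seasonal mean and amplitude of PAR,
#'   MJ m-2 d-1.
#' @return a named list classed `scene_config`.
#' @export
scene_config <- function(grid_width = 32, grid_height = 32, pixel_size = 30,
                         origin = c(0, grid_height * pixel_size),
                         years = c(2020, 2020), seed = 1L,
                         cloud_gap_fraction = 0.1, noise_sd = 0.01,
                         seasonal_amplitude = 0.25,
                         hemisphere = c("north", "south"),
                         lst_mean = 12, lst_amplitude = 14,
                         par_mean = 7, par_amplitude = 4) {
  stopifnot(grid_width >= 1, grid_height >= 1,
            cloud_gap_fraction >= 0, cloud_gap_fraction <= 1,
            noise_sd >= 0, length(years) == 2, years[2] >= years[1])
  structure(list(grid_width = grid_width, grid_height = grid_height,
                 pixel_size = pixel_size, origin = origin, years = years,
                 seed = as.integer(seed),
                 cloud_gap_fraction = cloud_gap_fraction,
                 noise_sd = noise_sd,
                 seasonal_amplitude = seasonal_amplitude,
                 hemisphere = match.arg(hemisphere),
                 lst_mean = lst_mean, lst_amplitude = lst_amplitude,
                 par_mean = par_mean, par_amplitude = par_amplitude),
            class = "scene_config")
}

scene_grid <- function(config) {
  lue_grid(config$grid_width, config$grid_height, config$pixel_size,
           origin = config$origin)
}

# seasonal phase: cosine peaking at the configured hemisphere's summer,
# evaluated at bimonthly period midpoints (period 1 = Jan-Feb, ...)
season_weight <- function(period, hemisphere) {
  peak <- if (hemisphere == "north") 4 else 1
  cos(2 * pi * (period - peak) / 6)
}

#' Generate a synthetic bimonthly reflectance cube
#'
#' Per-pixel seasonal NIR sinusoid (hemisphere-dependent phase) over a low,
#' flat red band so derived NDVI spans roughly \[0.05, 0.9\] through the
#' year; SWIR1 tracks an inverted, damped version of the greenness cycle so
#' LSWI peaks in the growing season. A `cloud_gap_fraction` of pixels per
#' period is flagged missing across all bands, and a per-period
#' `cloud_cover` vector is recorded as an attribute.
#'
#' @param config a [scene_config()].
#' @return a `refl_cube` with attribute `cloud_cover` (per period, in
#'   \[0,1\]).
#' @export
gen_reflectance <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  h <- config$grid_height; w <- config$grid_width
  yrs <- seq.int(config$years[1], config$years[2])
  periods <- expand.grid(period = 1:6, year = yrs)[, c("year", "period")]
  np <- nrow(periods)
  # static per-pixel fields: base greenness level and amplitude scaling
  base <- matrix(stats::runif(h * w, 0.30, 0.40), h, w)
  ampl <- config$seasonal_amplitude * matrix(stats::runif(h * w, 0.8, 1.2), h, w)
  red0 <- matrix(stats::runif(h * w, 0.04, 0.06), h, w)
  dims <- c(h, w, np)
  red <- array(NA_real_, dims); nir <- array(NA_real_, dims)
  swir1 <- array(NA_real_, dims)
  cloud_cover <- stats::runif(np, 0, 0.8) * (config$cloud_gap_fraction > 0)
  for (i in seq_len(np)) {
    s <- season_weight(periods$period[i], config$hemisphere)
    n_i <- base + ampl * s + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    r_i <- red0 + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    sw_i <- 0.22 - 0.10 * s * (ampl / max(config$seasonal_amplitude, 1e-12)) +
      matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    if (config$seasonal_amplitude == 0)
      sw_i <- matrix(0.22, h, w) + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    n_i <- pmin(pmax(n_i, 0), 1); r_i <- pmin(pmax(r_i, 0.001), 1)
    sw_i <- pmin(pmax(sw_i, 0), 1)
    if (config$cloud_gap_fraction > 0) {
      gap <- matrix(stats::runif(h * w) < config$cloud_gap_fraction, h, w)
      n_i[gap] <- NA_real_; r_i[gap] <- NA_real_; sw_i[gap] <- NA_real_
    }
    red[, , i] <- r_i; nir[, , i] <- n_i; swir1[, , i] <- sw_i
  }
  cube <- refl_cube(red, nir, swir1, periods, scene_grid(config))
  attr(cube, "cloud_cover") <- cloud_cover
  cube
}

#' Generate synthetic coarse climate drivers
#'
#' Smooth (low-spatial-frequency) coarse-grid land-surface-temperature and
#' PAR fields: LST on a nominal 8-day cadence with a seasonal cosine that
#' crosses 0 degC in winter when `lst_amplitude > lst_mean`, PAR monthly,
#' non-negative, peaking in the configured hemisphere's summer. Spatial
#' structure is a fixed gentle gradient plus a smooth random surface;
#' timestamps are window midpoints. Use `constant = list(lst =, par =)` for
#' exactly uniform fields.
#'
#' @param config a [scene_config()].
#' @param coarse_factor integer >= 1; coarse pixel size is
#'   `pixel_size * coarse_factor`.
#' @param constant optional list with `lst` and/or `par` values overriding
#'   the generator with spatially/temporally constant fields.
#' @return list with `lst` (list of matrices), `lst_dates`, `par`,
#'   `par_dates`, `grid` (the coarse [lue_grid()]).
#' @export
gen_climate <- function(config, coarse_factor = 8L, constant = NULL) {
  stopifnot(inherits(config, "scene_config"), coarse_factor >= 1)
  set.seed(config$seed + 1L)
  ch <- max(1L, ceiling(config$grid_height / coarse_factor))
  cw <- max(1L, ceiling(config$grid_width / coarse_factor))
  cgrid <- lue_grid(cw, ch, config$pixel_size * coarse_factor,
                    origin = config$origin)
  yrs <- seq.int(config$years[1], config$years[2])
  peak_doy <- if (config$hemisphere == "north") 200 else 15
  # fixed smooth spatial anomaly shared by all time steps
  gx <- outer(seq_len(ch), seq_len(cw), function(r, cc) {
    0.5 * sin(pi * r / (ch + 1)) * cos(pi * cc / (cw + 1))
  })
  lst <- list(); lst_dates <- as.Date(character())
  par_l <- list(); par_dates <- as.Date(character())
  for (y in yrs) {
    d0 <- as.Date(sprintf("%d-01-01", y))
    starts <- seq(d0, as.Date(sprintf("%d-12-31", y)), by = 8)
    for (s in seq_along(starts)) {
      doy <- as.integer(format(starts[s], "%j")) + 4  # window midpoint
      val <- config$lst_mean +
        config$lst_amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
      lst[[length(lst) + 1L]] <- matrix(val, ch, cw) + gx
      lst_dates <- c(lst_dates, starts[s] + 4)
    }
    for (m in 1:12) {
      mid <- as.Date(sprintf("%d-%02d-15", y, m))
      doy <- as.integer(format(mid, "%j"))
      val <- max(0, config$par_mean +
                   config$par_amplitude * cos(2 * pi * (doy - peak_doy) / 365.25))
      par_l[[length(par_l) + 1L]] <- pmax(matrix(val, ch, cw) + 0.3 * gx, 0)
      par_dates <- c(par_dates, mid)
    }
  }
  if (!is.null(constant$lst))
    lst <- lapply(lst, function(m) matrix(constant$lst, ch, cw))
  if (!is.null(constant$par))
    par_l <- lapply(par_l, function(m) matrix(constant$par, ch, cw))
  list(lst = lst, lst_dates = lst_dates, par = par_l, par_dates = par_dates,
       grid = cgrid)
}

#' Generate annual grassland masks
#'
#' Spatially autocorrelated binary masks: a smooth random surface
#' (moving-average-blurred white noise) thresholded at the quantile giving
#' the requested grassland share; the realized share is within a few
#' percentage points of `fraction` and is recorded as an attribute. One mask
#' per year; the extent evolves slowly between years.
#'
#' @param config a [scene_config()].
#' @param fraction target grassland pixel share in \[0,1\].
#' @return named list of binary matrices (one per year, names = years),
#'   each with attribute `share` (the realized fraction).
#' @export
gen_grassland_mask <- function(config, fraction = 0.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(config$seed + 2L)
  h <- config$grid_height; w <- config$grid_width
  yrs <- seq.int(config$years[1], config$years[2])
  blur <- function(m) {
    p <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    p <- cbind(p[, 1, drop = FALSE], p, p[, ncol(p), drop = FALSE])
    (p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
       p[2:(h + 1), 1:w] + p[2:(h + 1), 2:(w + 1)] + p[2:(h + 1), 3:(w + 2)] +
       p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]) / 9
  }
  surf <- matrix(stats::rnorm(h * w), h, w)
  for (k in 1:4) surf <- blur(surf)
  out <- list()
  for (y in yrs) {
    surf <- surf + 0.05 * blur(matrix(stats::rnorm(h * w), h, w))
    if (fraction == 0) mask <- matrix(0L, h, w)
    else if (fraction == 1) mask <- matrix(1L, h, w)
    else {
      thr <- stats::quantile(surf, 1 - fraction, names = FALSE)
      mask <- matrix(as.integer(surf > thr), h, w)
    }
    attr(mask, "share") <- mean(mask)
    out[[as.character(y)]] <- mask
  }
  out
}

#' Flux tower configuration
#'
#' @param site_id site label.
#' @param location length-2 x/y coordinates on or near the scene grid.
#' @param land_cover_class IGBP code present in the biome lookup table.
#' @param years inclusive year range.
#' @param gapfill_fraction target fraction of gap-filled days, \[0,1\].
#' @param dtnt_noise_sd gC m-2 d-1 spread between the day-time and
#'   night-time partitioning estimates.
#' @param seed integer RNG seed.
#' @param lut a [biome_lut()] used to validate `land_cover_class`.
#' @return a named list classed `tower_config`.
#' @export
tower_config <- function(site_id, location, land_cover_class = "GRA",
                         years = c(2020, 2020), gapfill_fraction = 0,
                         dtnt_noise_sd = 0, seed = 1L, lut = biome_lut()) {
  stopifnot(gapfill_fraction >= 0, gapfill_fraction <= 1,
            land_cover_class %in% names(lut), length(location) == 2)
  structure(list(site_id = site_id, location = as.numeric(location),
                 land_cover_class = land_cover_class, years = years,
                 gapfill_fraction = gapfill_fraction,
                 dtnt_noise_sd = dtnt_noise_sd, seed = as.integer(seed)),
            class = "tower_config")
}

#' Generate a synthetic daily flux-tower GPP series
#'
#' Emulates the outputs of day-time/night-time flux partitioning around a
#' known daily truth: `gpp_dt = truth + noise`, `gpp_nt = truth +
#' independent noise` (sd `dtnt_noise_sd`), a `gapfill_fraction` of days
#' flagged gap-filled, and optionally `inject_discrepant_days` days forced
#' to |DT - NT| > 3 gC m-2 d-1 to exercise the consistency filter.
#'
#' @param tower a [tower_config()].
#' @param truth data.frame with `date` and `gpp` (daily truth) covering the
#'   configured years.
#' @param inject_discrepant_days integer count of days to force discrepant.
#' @return data.frame `date, gpp_dt, gpp_nt, gapfill_flag` with attributes
#'   `site_id`, `location`, `land_cover_class`.
#' @export
gen_tower_series <- function(tower, truth, inject_discrepant_days = 0L) {
  stopifnot(inherits(tower, "tower_config"),
            all(c("date", "gpp") %in% names(truth)))
  set.seed(tower$seed)
  d0 <- as.Date(sprintf("%d-01-01", tower$years[1]))
  d1 <- as.Date(sprintf("%d-12-31", tower$years[2]))
  dates <- seq(d0, d1, by = 1)
  tr <- truth$gpp[match(dates, as.Date(truth$date))]
  if (anyNA(tr)) stop("truth series does not cover the configured years")
  n <- length(dates)
  dt <- tr + stats::rnorm(n, 0, tower$dtnt_noise_sd)
  nt <- tr + stats::rnorm(n, 0, tower$dtnt_noise_sd)
  gap <- rep(0L, n)
  ngap <- round(tower$gapfill_fraction * n)
  if (ngap > 0) gap[sample.int(n, ngap)] <- 1L
  if (inject_discrepant_days > 0) {
    # make days discrepant, leaving all others within the 3-unit band
    delta <- abs(dt - nt)
    eligible <- which(delta <= 3)
    pick <- sample(eligible, inject_discrepant_days)
    nt[pick] <- dt[pick] + 3.5
  }
  out <- data.frame(date = dates, gpp_dt = dt, gpp_nt = nt,
                    gapfill_flag = gap)
  attr(out, "site_id") <- tower$site_id
  attr(out, "location") <- tower$location
  attr(out, "land_cover_class") <- tower$land_cover_class
  out
}

#' Daily truth series from a model GPP cube at a tower footprint
#'
#' The known-answer path for validation: the daily truth at a tower is the
#' footprint mean of the model's bimonthly GPP, held constant within each
#' period. Feeding this truth to [gen_tower_series()] with zero noise makes
#' the end-to-end validation exact (r = 1, RMSE = 0).
#'
#' @param cube a bimonthly `gpp_cube` with a grid.
#' @param location tower x/y.
#' @param radius footprint radius in grid units, default 250.
#' @param land_cover_class optional IGBP code; when given (and the cube is
#'   uncalibrated), the truth is expressed in tower-comparable units by
#'   applying the biome maximum-LUE factor.
#' @param lut a [biome_lut()].
#' @return data.frame `date`, `gpp` spanning the cube's years.
#' @export
tower_truth_from_gpp <- function(cube, location, radius = 250,
                                 land_cover_class = NULL, lut = biome_lut()) {
  fm <- footprint_mean(cube, location, radius = radius)
  if (!is.null(land_cover_class))
    fm$model <- calibrate_by_landcover(fm$model, land_cover_class, lut)
  yrs <- range(cube$periods$year)
  dates <- seq(as.Date(sprintf("%d-01-01", yrs[1])),
               as.Date(sprintf("%d-12-31", yrs[2])), by = 1)
  pp <- period_of_date(dates)
  key <- period_key(pp$year, pp$period)
  gpp <- fm$model[match(key, period_key(fm$year, fm$period))]
  data.frame(date = dates, gpp = gpp)
}
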