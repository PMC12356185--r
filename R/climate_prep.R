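#' Temporal compositing to the bimonthly calendar
#'
#' Averages a timestamped raster series (e.g. 8-day land-surface-temperature
#' composites or monthly radiation fields) into per-period means. A raster
#' belongs to the period whose half-open interval `[start, end)` contains its
#' nominal timestamp; composites spanning several days should be stamped with
#' their window midpoint before calling. Periods with no inputs produce an
#' all-NA raster and a warning.
#'
#' @param rasters list of aligned matrices.
#' @param dates Date vector of nominal timestamps, one per raster.
#' @param calendar a [bimonthly_calendar()].
#' @return 3-D array \[rows, cols, periods\] ordered as `calendar`, with the
#'   calendar attached as attribute `"periods"`.
#' @export
bimonthly_mean <- function(rasters, dates, calendar) {
  stopifnot(length(rasters) == length(dates), inherits(calendar, "bimonthly_calendar"))
  dates <- as.Date(dates)
  dm <- dim(rasters[[1]])
  out <- array(NA_real_, c(dm[1], dm[2], nrow(calendar)))
  for (i in seq_len(nrow(calendar))) {
    idx <- which(dates >= calendar$start[i] & dates < calendar$end[i])
    if (length(idx) == 0L) {
      warning("no inputs for period ", period_key(calendar$year[i], calendar$period[i]),
              call. = FALSE)
      next
    }
    acc <- Reduce(`+`, rasters[idx]) / length(idx)
    out[, , i] <- acc
  }
  attr(out, "periods") <- calendar[, c("year", "period")]
  out
}

#' Cloud-cover-weighted bimonthly reflectance compositing
#'
#' Composites ~16-day scenes into bimonthly reflectance, weighting each
#' scene by `w = 1 - cloud_cover` (clearer scenes weigh more) and
#' renormalizing per pixel over the scenes where that pixel is clear
#' (non-NA). A pixel clear in no scene stays NA. If every contributing
#' scene at a clear pixel has weight 0, the composite falls back to the
#' unweighted mean with a warning.
#'
#' @param scenes list of scenes; each a list with matrices `red`, `nir`,
#'   `swir1`, a `date` (Date) and `cloud_cover` in \[0,1\].
#' @param calendar a [bimonthly_calendar()].
#' @param grid the scene [lue_grid()].
#' @return a `refl_cube`: list of 3-D arrays `red`, `nir`, `swir1`
#'   \[rows, cols, periods\], `periods` data.frame, `grid`.
#' @export
composite_reflectance <- function(scenes, calendar, grid = NULL) {
  stopifnot(length(scenes) > 0, inherits(calendar, "bimonthly_calendar"))
  cc <- vapply(scenes, function(s) s$cloud_cover, 0)
  stopifnot(all(cc >= 0 & cc <= 1))
  dates <- as.Date(vapply(scenes, function(s) as.character(s$date), ""))
  dm <- dim(scenes[[1]]$red)
  bands <- c("red", "nir", "swir1")
  cube <- lapply(bands, function(b) array(NA_real_, c(dm[1], dm[2], nrow(calendar))))
  names(cube) <- bands
  zero_w_fallback <- FALSE
  for (i in seq_len(nrow(calendar))) {
    idx <- which(dates >= calendar$start[i] & dates < calendar$end[i])
    if (length(idx) == 0L) next
    w <- 1 - cc[idx]
    for (b in bands) {
      vals <- lapply(scenes[idx], `[[`, b)
      wsum <- matrix(0, dm[1], dm[2])
      acc <- matrix(0, dm[1], dm[2])
      nclear <- matrix(0L, dm[1], dm[2])
      usum <- matrix(0, dm[1], dm[2])
      for (k in seq_along(idx)) {
        v <- vals[[k]]
        clear <- !is.na(v)
        wsum[clear] <- wsum[clear] + w[k]
        acc[clear] <- acc[clear] + w[k] * v[clear]
        usum[clear] <- usum[clear] + v[clear]
        nclear[clear] <- nclear[clear] + 1L
      }
      comp <- acc / wsum
      degenerate <- nclear > 0L & wsum == 0
      if (any(degenerate)) {
        zero_w_fallback <- TRUE
        comp[degenerate] <- usum[degenerate] / nclear[degenerate]
      }
      comp[nclear == 0L] <- NA_real_
      cube[[b]][, , i] <- comp
    }
  }
  if (zero_w_fallback)
    warning("all scene weights zero at some clear pixels; used unweighted mean",
            call. = FALSE)
  refl_cube(cube$red, cube$nir, cube$swir1,
            calendar[, c("year", "period")], grid)
}

#' Reflectance cube constructor
#'
#' Bundles aligned per-period red/NIR/SWIR1 stacks with their period axis
#' and grid. A pixel missing in any band is treated as missing in every
#' derived index downstream.
#'
#' @param red,nir,swir1 3-D arrays \[rows, cols, periods\].
#' @param periods data.frame with `year`, `period` per slice.
#' @param grid a [lue_grid()] or NULL.
#' @return an object of class `refl_cube`.
#' @export
refl_cube <- function(red, nir, swir1, periods, grid = NULL) {
  stopifnot(identical(dim(red), dim(nir)), identical(dim(red), dim(swir1)),
            dim(red)[3] == nrow(periods))
  structure(list(red = red, nir = nir, swir1 = swir1,
                 periods = as.data.frame(periods), grid = grid),
            class = "refl_cube")
}

#' @export
print.refl_cube <- function(x, ...) {
  dm <- dim(x$red)
  cat(sprintf("<refl_cube> %d x %d px, %d periods (%d-%d), %.1f%% missing\n",
              dm[1], dm[2], dm[3], min(x$periods$year), max(x$periods$year),
              100 * mean(is.na(x$red))))
  invisible(x)
}

# 1-D natural cubic spline sampled at xout, with coordinates clamped to the
# data hull (nearest-value extension, no extrapolated overshoot)
spline_clamped <- function(x, y, xout) {
  ok <- !is.na(y)
  if (sum(ok) == 0L) return(rep(NA_real_, length(xout)))
  if (sum(ok) == 1L) return(rep(y[ok], length(xout)))
  xo <- pmin(pmax(xout, min(x[ok])), max(x[ok]))
  stats::spline(x[ok], y[ok], xout = xo, method = "natural")$y
}

#' Downscale a coarse raster to a fine grid by cubic splines
#'
#' Tensor-product natural cubic spline interpolation of coarse cell-center
#' values onto the target pixel centers (column pass then row pass). Beyond
#' the coarse hull the nearest in-hull coordinate is used, avoiding
#' nonphysical overshoot at edges; NA coarse cells are dropped from each 1-D
#' fit. Constants are reproduced exactly and linear fields to numerical
#' tolerance.
#'
#' @param coarse matrix of coarse values.
#' @param coarse_grid,target_grid [lue_grid()] descriptors.
#' @param lower optional lower bound; interpolated values below it are
#'   clamped (e.g. 0 for radiation) with a message reporting the count.
#' @return matrix on the target grid.
#' @export
downscale <- function(coarse, coarse_grid, target_grid, lower = NULL) {
  xs <- grid_xcoords(coarse_grid); ys <- grid_ycoords(coarse_grid)
  xt <- grid_xcoords(target_grid); yt <- grid_ycoords(target_grid)
  # pass 1: along columns (x) for each coarse row
  mid <- matrix(NA_real_, nrow(coarse), length(xt))
  for (r in seq_len(nrow(coarse))) mid[r, ] <- spline_clamped(xs, coarse[r, ], xt)
  # pass 2: along rows (y) for each target column
  out <- matrix(NA_real_, length(yt), length(xt))
  for (cc in seq_len(ncol(mid))) out[, cc] <- spline_clamped(ys, mid[, cc], yt)
  if (!is.null(lower)) {
    nneg <- sum(out < lower, na.rm = TRUE)
    if (nneg > 0) {
      message(nneg, " downscaled values below ", lower, " clamped")
      out[!is.na(out) & out < lower] <- lower
    }
  }
  out
}

#' Causal same-season gap fill
#'
#' Pluggable stand-in for the external seasonally-weighted time-series
#' reconstruction this pipeline consumes upstream: each missing pixel-period
#' is filled with the most recent valid value from the same bimonth-of-year
#' in PAST years only (respecting causality); remaining gaps stay NA.
#'
#' @param cube a `refl_cube`.
#' @return a `refl_cube` with past-season fills applied per band.
#' @export
gapfill_passthrough <- function(cube) {
  stopifnot(inherits(cube, "refl_cube"))
  ord <- order(cube$periods$year, cube$periods$period)
  for (b in c("red", "nir", "swir1")) {
    arr <- cube[[b]]
    for (p in 1:6) {
      idx <- ord[cube$periods$period[ord] == p]
      if (length(idx) < 2L) next
      for (j in seq_along(idx)[-1]) {
        cur <- arr[, , idx[j]]
        if (!anyNA(cur)) next
        for (k in rev(seq_len(j - 1L))) {
          miss <- is.na(cur)
          if (!any(miss)) break
          past <- arr[, , idx[k]]
          fill <- miss & !is.na(past)
          cur[fill] <- past[fill]
        }
        arr[, , idx[j]] <- cur
      }
    }
    cube[[b]] <- arr
  }
  cube
}

#' Assemble a bimonthly climate cube on the fine grid
#'
#' Convenience wrapper chaining [bimonthly_mean()] and [downscale()] for the
#' two drivers: land surface temperature (degrees C, nominally 8-day) and
#' photosynthetically active radiation (MJ m-2 d-1, nominally monthly).
#' Radiation is clamped at 0 after interpolation.
#'
#' @param lst_rasters,lst_dates coarse LST series and midpoint timestamps.
#' @param par_rasters,par_dates coarse PAR series and midpoint timestamps.
#' @param coarse_grid,target_grid [lue_grid()] descriptors.
#' @param calendar a [bimonthly_calendar()].
#' @return a `climate_cube`: list with 3-D arrays `lst`, `par` on the target
#'   grid, `periods`, `grid`.
#' @export
prepare_climate <- function(lst_rasters, lst_dates, par_rasters, par_dates,
                            coarse_grid, target_grid, calendar) {
  lst_bm <- bimonthly_mean(lst_rasters, lst_dates, calendar)
  par_bm <- bimonthly_mean(par_rasters, par_dates, calendar)
  np <- nrow(calendar)
  lst_f <- array(NA_real_, c(target_grid$height, target_grid$width, np))
  par_f <- array(NA_real_, c(target_grid$height, target_grid$width, np))
  for (i in seq_len(np)) {
    if (!all(is.na(lst_bm[, , i])))
      lst_f[, , i] <- downscale(lst_bm[, , i], coarse_grid, target_grid)
    if (!all(is.na(par_bm[, , i])))
      par_f[, , i] <- downscale(par_bm[, , i], coarse_grid, target_grid, lower = 0)
  }
  structure(list(lst = lst_f, par = par_f,
                 periods = calendar[, c("year", "period")], grid = target_grid),
            class = "climate_cube")
}

#' Convert shortwave flux density to daily PAR totals
#'
#' W m-2 to MJ m-2 d-1 (x 86400 s / 1e6).
#' @param x flux density in W m-2.
#' @return MJ m-2 d-1.
#' @export
wm2_to_mj_day <- function(x) {
  message("converting W m-2 to MJ m-2 d-1 (x 0.0864)")
  x * 0.0864
}

#' Convert scaled-Kelvin land surface temperature to degrees Celsius
#'
#' Reader-side preprocessing for products stored as Kelvin x 50 integers
#' (scale 0.02): `x * 0.02 - 273.15`.
#' @param x stored integers.
#' @return degrees C.
#' @export
lst_k02_to_celsius <- function(x) {
  message("converting scaled Kelvin (x0.02) to degrees C")
  x * 0.02 - 273.15
}
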