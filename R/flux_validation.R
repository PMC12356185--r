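#' Gap-fill quality screening of a tower series
#'
#' A series is usable when gap-filled days make up no more than
#' `max_gapfill` of the total time series (boundary inclusive: exactly 20%
#' is accepted with the default).
#'
#' @param series data.frame with a `gapfill_flag` column (0/1).
#' @param max_gapfill acceptance threshold, default 0.20.
#' @return logical: accept (`TRUE`) or reject.
#' @export
screen_series <- function(series, max_gapfill = 0.20) {
  stopifnot(nrow(series) > 0, "gapfill_flag" %in% names(series))
  mean(series$gapfill_flag) <= max_gapfill
}

#' Day-time/night-time consistency filtering
#'
#' Discards daily records where the day-time and night-time partitioning
#' estimates differ by strictly more than `max_dtnt_gap` gC m-2 d-1
#' (a gap of exactly 3 is kept). Idempotent.
#'
#' @param series data.frame with `gpp_dt`, `gpp_nt`.
#' @param max_dtnt_gap threshold, default 3.
#' @return the filtered data.frame.
#' @export
filter_days <- function(series, max_dtnt_gap = 3) {
  keep <- abs(series$gpp_dt - series$gpp_nt) <= max_dtnt_gap
  series[keep, , drop = FALSE]
}

#' Bimonthly median of daily tower GPP
#'
#' Aggregates surviving daily day-time GPP values to the model's temporal
#' grid by the per-period median (even counts use the midpoint of the two
#' central values); periods with no surviving days are absent from the
#' result.
#'
#' @param series data.frame with `date` and the value column.
#' @param value column to aggregate, default `"gpp_dt"` (the compared
#'   quantity).
#' @return data.frame `year`, `period`, `observed`.
#' @export
bimonthly_median <- function(series, value = "gpp_dt") {
  stopifnot(value %in% names(series))
  pp <- period_of_date(series$date)
  key <- period_key(pp$year, pp$period)
  med <- tapply(series[[value]], key, stats::median)
  ky <- names(med)
  yr <- as.integer(sub("_p.*", "", ky))
  pd <- as.integer(sub(".*_p", "", ky))
  o <- order(yr, pd)
  data.frame(year = yr[o], period = pd[o], observed = as.numeric(med)[o])
}

#' Footprint mean of model GPP around a tower
#'
#' Per period, the unweighted mean of valid dequantized GPP over the pixels
#' whose centers lie within `radius` of the tower (distances in the grid's
#' projected units; pixel-center-in-circle membership). Periods with no
#' valid pixel in the disc are absent from the result.
#'
#' @param cube a `gpp_cube` with a grid.
#' @param location tower x/y in grid coordinates.
#' @param radius footprint radius, default 250 (metres on a 30 m grid).
#' @param site_id label used in error messages.
#' @return data.frame `year`, `period`, `model`.
#' @export
footprint_mean <- function(cube, location, radius = 250, site_id = "site") {
  stopifnot(inherits(cube, "gpp_cube"), !is.null(cube$grid),
            !is.null(cube$periods))
  ext <- grid_extent(cube$grid)
  if (location[1] < ext["xmin"] || location[1] > ext["xmax"] ||
      location[2] < ext["ymin"] || location[2] > ext["ymax"])
    stop("tower ", site_id, " lies outside the raster extent", call. = FALSE)
  dx <- grid_xcoords(cube$grid) - location[1]
  dy <- grid_ycoords(cube$grid) - location[2]
  d2 <- outer(dy^2, dx^2, `+`)  # [row, col]
  inside <- d2 <= radius^2
  if (!any(inside))
    stop("footprint of ", site_id, " contains no pixel center", call. = FALSE)
  vals <- dequantize(cube)
  out <- cube$periods
  out$model <- vapply(seq_len(nrow(out)), function(i) {
    v <- vals[, , i][inside]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  out[!is.na(out$model), , drop = FALSE]
}

#' Validation accuracy statistics
#'
#' Pearson's r, R-squared, RMSE and bias for matched (model, observed)
#' pairs. Bias is model minus observed. By default R-squared is the squared
#' Pearson correlation; `r2 = "one_to_one"` instead reports
#' `1 - SSres/SStot` about the 1:1 line. If either vector has zero
#' variance, r and R-squared are NA while RMSE and bias are still computed.
#'
#' @param model,observed numeric vectors of equal length >= 2.
#' @param r2 `"pearson"` (default) or `"one_to_one"`.
#' @return list classed `validation_report`: `n`, `pearson_r`, `r2`,
#'   `rmse`, `bias`.
#' @export
compute_metrics <- function(model, observed, r2 = c("pearson", "one_to_one")) {
  r2 <- match.arg(r2)
  stopifnot(length(model) == length(observed))
  ok <- !is.na(model) & !is.na(observed)
  m <- model[ok]; o <- observed[ok]
  n <- length(m)
  if (n < 2) stop("need at least 2 matched pairs", call. = FALSE)
  r <- if (stats::sd(m) == 0 || stats::sd(o) == 0) NA_real_ else stats::cor(m, o)
  r2v <- if (r2 == "pearson") r^2 else {
    sst <- sum((o - mean(o))^2)
    if (sst == 0) NA_real_ else 1 - sum((m - o)^2) / sst
  }
  structure(list(n = n, pearson_r = r, r2 = r2v,
                 rmse = sqrt(mean((m - o)^2)), bias = mean(m - o)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("n = %d, r = %s, R2 = %s, RMSE = %.3f, bias = %+.3f gC m-2 d-1\n",
              x$n,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)),
              x$rmse, x$bias))
  invisible(x)
}

#' Match model footprints to tower observations at one site
#'
#' Runs the full per-site protocol: gap-fill screening, day-time/night-time
#' consistency filtering, bimonthly medians of the day-time product,
#' footprint means of the model cube, per-site biome calibration of the
#' uncalibrated model values, and pairing on periods where both sides are
#' present.
#'
#' @param cube a bimonthly uGPP `gpp_cube`.
#' @param series a daily tower data.frame (see [gen_tower_series()]), with
#'   attributes `site_id`, `location`, `land_cover_class` (or pass them).
#' @param site_id,location,land_cover_class overrides for the attributes.
#' @param network optional network label carried into the pairs.
#' @param lut a [biome_lut()].
#' @param radius footprint radius, default 250.
#' @param max_gapfill,max_dtnt_gap QC thresholds.
#' @return data.frame of matched pairs (`site_id, network, igbp, year,
#'   period, model, observed`), zero rows if the series is rejected.
#' @export
match_tower <- function(cube, series,
                        site_id = attr(series, "site_id"),
                        location = attr(series, "location"),
                        land_cover_class = attr(series, "land_cover_class"),
                        network = "synthetic", lut = biome_lut(),
                        radius = 250, max_gapfill = 0.20, max_dtnt_gap = 3) {
  empty <- data.frame(site_id = character(), network = character(),
                      igbp = character(), year = integer(), period = integer(),
                      model = numeric(), observed = numeric())
  if (!screen_series(series, max_gapfill)) return(empty)
  kept <- filter_days(series, max_dtnt_gap)
  if (nrow(kept) == 0) return(empty)
  obs <- bimonthly_median(kept)
  mod <- footprint_mean(cube, location, radius = radius, site_id = site_id)
  mod$model <- calibrate_by_landcover(mod$model, land_cover_class, lut)
  pairs <- merge(mod, obs, by = c("year", "period"))
  if (nrow(pairs) == 0) return(empty)
  data.frame(site_id = site_id, network = network,
             igbp = land_cover_class, year = pairs$year,
             period = pairs$period, model = pairs$model,
             observed = pairs$observed)
}

#' Stratified validation report
#'
#' Pools matched pairs from many towers and reports accuracy statistics per
#' stratum — by network, by land-cover class — plus the pooled "All" row.
#' Strata with fewer than 2 pairs are omitted with a message.
#'
#' @param pairs data.frame of matched pairs from [match_tower()]
#'   (row-bound across sites).
#' @param strata which groupings to report, subset of
#'   `c("network", "igbp")`.
#' @return data.frame `stratum, n, pearson_r, r2, rmse, bias`.
#' @export
stratified_report <- function(pairs, strata = c("network", "igbp")) {
  stopifnot(nrow(pairs) >= 2)
  rows <- list()
  add <- function(label, idx) {
    if (length(idx) < 2) {
      message("stratum ", label, " has < 2 pairs; omitted")
      return()
    }
    m <- compute_metrics(pairs$model[idx], pairs$observed[idx])
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum = label, n = m$n, pearson_r = m$pearson_r, r2 = m$r2,
      rmse = m$rmse, bias = m$bias)
  }
  add("All", seq_len(nrow(pairs)))
  for (s in strata)
    for (g in unique(pairs[[s]]))
      add(paste0(s, ":", g), which(pairs[[s]] == g))
  do.call(rbind, rows)
}
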