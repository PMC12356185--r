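#' Write a quantized GPP slice as a 16-bit TIFF with sidecar metadata
#'
#' One slice per file, following the cloud-optimized-GeoTIFF convention of
#' integer pixels plus metadata: the TIFF holds the stored 16-bit integers
#' (nodata 65535) and a JSON sidecar (`<path>.json`) carries the
#' geotransform, CRS, `scale_factor`, `units` and `nodata` tags.
#'
#' @param cube a `gpp_cube` with a grid.
#' @param slice slice index (period or year position), default 1.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_gpp_tif <- function(cube, path, slice = 1L) {
  stopifnot(inherits(cube, "gpp_cube"), !is.null(cube$grid))
  stored <- if (length(dim(cube$stored)) == 3) cube$stored[, , slice] else cube$stored
  img <- stored
  img[is.na(img)] <- cube$nodata
  if (any(img > 65535L)) stop("stored value exceeds 16-bit range")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  meta <- list(
    width = cube$grid$width, height = cube$grid$height,
    pixel_size = cube$grid$pixel_size, origin = cube$grid$origin,
    crs = cube$grid$crs, scale_factor = cube$scale, units = cube$units,
    nodata = cube$nodata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a GPP slice written by [write_gpp_tif()]
#'
#' @param path the `.tif` path (the `.json` sidecar must sit next to it).
#' @return a single-slice `gpp_cube`.
#' @export
read_gpp_tif <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  stored <- round(img * 65535)
  storage.mode(stored) <- "integer"
  stored[stored == meta$nodata] <- NA_integer_
  grid <- lue_grid(meta$width, meta$height, meta$pixel_size,
                   origin = meta$origin, crs = meta$crs)
  gpp_cube(stored, scale = meta$scale_factor, grid = grid,
           units = meta$units)
}

#' Write a tower series CSV
#'
#' Columns `date` (ISO-8601), `gpp_dt`, `gpp_nt` (gC m-2 d-1),
#' `gapfill_flag` (0/1).
#'
#' @param series tower data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tower_csv <- function(series, path) {
  utils::write.csv(series[, c("date", "gpp_dt", "gpp_nt", "gapfill_flag")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a tower series CSV
#'
#' @param path CSV with columns `date,gpp_dt,gpp_nt,gapfill_flag`.
#' @return data.frame with `date` parsed as Date.
#' @export
read_tower_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "gpp_dt", "gpp_nt", "gapfill_flag") %in% names(df)))
  df$date <- as.Date(df$date)
  df
}
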