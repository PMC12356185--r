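#' Biome maximum-LUE lookup table
#'
#' Maps IGBP land-cover class codes to the biome-specific theoretical
#' maximum light-use efficiency (gC m-2 d-1 MJ-1), the globally adjusted
#' values of the MOD17 biome property lookup table. The shipped default is
#' read from the package's CSV (`class_code,class_name,eps_luemax`);
#' grasslands (GRA) map to 0.860.
#'
#' @param path optional CSV path; defaults to the packaged table.
#' @return named numeric vector (names = IGBP codes), classed `biome_lut`.
#' @examples
#' biome_lut()[["GRA"]]  # 0.86
#' @export
biome_lut <- function(path = system.file("extdata", "biome_lut.csv",
                                         package = "grasslue")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class_code", "eps_luemax") %in% names(df)),
            all(df$eps_luemax > 0))
  structure(stats::setNames(df$eps_luemax, df$class_code),
            class_name = df$class_name, class = "biome_lut")
}

#' Bimonthly uncalibrated GPP
#'
#' The LUE model kernel with the maximum-LUE factor fixed at
#' 1 gC m-2 d-1 MJ-1: `uGPP = PAR * fAPAR * (1 * T_scalar * W_scalar)`.
#' Biome calibration is deferred to a metadata scale factor so any
#' land-cover product can calibrate the same stored integers. NA propagates
#' from any input.
#'
#' @param par PAR, MJ m-2 d-1.
#' @param fapar absorbed fraction in \[0, 1\].
#' @param ts,ws temperature and water scalars in \[0, 1\].
#' @return uGPP in gC m-2 d-1 per unit maximum LUE.
#' @export
ugpp <- function(par, fapar, ts, ws) {
  check_aligned(par, fapar, ts, ws)
  par * fapar * ts * ws
}

#' Quantize GPP to integer storage
#'
#' Stores `round(value / step)` (round-half-even) as integers with the
#' storage step recorded as the metadata `scale`; physical value = stored
#' integer x scale, exactly. Biome calibration factors are composed into the
#' metadata scale (see [calibrate_grassland()]), never into the stored
#' integers. Negative inputs are clamped to 0 with a reported count.
#'
#' @param values real GPP array (2-D or 3-D), gC m-2 d-1.
#' @param step storage step, default 0.1.
#' @param periods data.frame `year`/`period` per slice (or `years` for
#'   annual cubes).
#' @param grid a [lue_grid()] or NULL.
#' @param units unit string recorded in metadata.
#' @return a `gpp_cube`.
#' @export
quantize <- function(values, step = 0.1, periods = NULL, grid = NULL,
                     units = "gC m-2 d-1") {
  stopifnot(step > 0)
  nneg <- sum(values < 0, na.rm = TRUE)
  if (nneg > 0) {
    message(nneg, " negative GPP values clamped to 0 before quantization")
    values[!is.na(values) & values < 0] <- 0
  }
  stored <- round(values / step)
  storage.mode(stored) <- "integer"
  gpp_cube(stored, scale = step, periods = periods, grid = grid, units = units)
}

#' Integer-quantized GPP cube
#'
#' Container for integer-stored GPP with scale-factor metadata, mirroring
#' the cloud-optimized GeoTIFF convention: `physical = stored * scale`.
#' Storage is unsigned-16-bit-compatible (0..65534, nodata 65535 on disk;
#' NA in memory).
#'
#' @param stored integer array (2-D or 3-D), >= 0 or NA.
#' @param scale metadata scale factor (> 0): 0.1 for uGPP, 0.086 for
#'   grassland-calibrated GPP.
#' @param periods per-slice `year`/`period` data.frame (bimonthly) or NULL.
#' @param years per-slice year vector (annual cubes) or NULL.
#' @param grid a [lue_grid()] or NULL.
#' @param units `"gC m-2 d-1"` (bimonthly) or `"gC m-2 yr-1"` (annual).
#' @return an object of class `gpp_cube`.
#' @export
gpp_cube <- function(stored, scale, periods = NULL, years = NULL, grid = NULL,
                     units = "gC m-2 d-1") {
  stopifnot(scale > 0, all(stored >= 0L, na.rm = TRUE))
  structure(list(stored = stored, scale = scale, periods = periods,
                 years = years, grid = grid, units = units,
                 nodata = 65535L),
            class = "gpp_cube")
}

#' Recover physical GPP values from a quantized cube
#'
#' @param cube a `gpp_cube`.
#' @return real array, `stored * scale`.
#' @export
dequantize <- function(cube) {
  stopifnot(inherits(cube, "gpp_cube"))
  cube$stored * cube$scale
}

#' @export
print.gpp_cube <- function(x, ...) {
  dm <- dim(x$stored); if (is.null(dm)) dm <- c(length(x$stored), 1, 1)
  nsl <- if (length(dm) == 3) dm[3] else 1
  cat(sprintf("<gpp_cube> %d x %d px, %d slice(s), scale %g, units %s\n",
              dm[1], dm[2], nsl, x$scale, x$units))
  v <- dequantize(x)
  cat(sprintf("  range %.2f-%.2f, %.1f%% nodata\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), 100 * mean(is.na(v))))
  invisible(x)
}

#' Calibrate uGPP for the grassland biome
#'
#' Masks the uGPP cube to each year's grassland extent and composes the
#' grassland maximum-LUE factor into the metadata scale: stored integers
#' inside the mask are copied unchanged, the output scale becomes
#' `scale * lut["GRA"]` (0.1 x 0.860 = 0.086 with the defaults), and pixels
#' outside the mask become nodata. Calibration is thus a pure metadata/mask
#' operation on the stored integers.
#'
#' @param cube a bimonthly uGPP `gpp_cube`.
#' @param masks named list of binary matrices, one per year (`"2020"` etc.).
#' @param lut a [biome_lut()].
#' @return a grassland-calibrated `gpp_cube`.
#' @export
calibrate_grassland <- function(cube, masks, lut = biome_lut()) {
  stopifnot(inherits(cube, "gpp_cube"), !is.null(cube$periods))
  stored <- cube$stored
  for (i in seq_len(dim(stored)[3])) {
    yr <- as.character(cube$periods$year[i])
    if (is.null(masks[[yr]]))
      stop("no grassland mask for year ", yr, call. = FALSE)
    sl <- stored[, , i]
    sl[masks[[yr]] == 0] <- NA_integer_
    stored[, , i] <- sl
  }
  gpp_cube(stored, scale = cube$scale * lut[["GRA"]], periods = cube$periods,
           grid = cube$grid, units = cube$units)
}

#' Calibrate uGPP values by land-cover class
#'
#' Point-scale calibration used when comparing uGPP against flux towers of
#' known IGBP class: `ugpp_value * lut[class]`.
#'
#' @param ugpp_value uGPP value(s), gC m-2 d-1.
#' @param class_code IGBP code present in `lut`.
#' @param lut a [biome_lut()].
#' @return calibrated GPP, gC m-2 d-1.
#' @export
calibrate_by_landcover <- function(ugpp_value, class_code, lut = biome_lut()) {
  if (!class_code %in% names(lut))
    stop("unknown land-cover class '", class_code, "'; valid codes: ",
         paste(names(lut), collapse = ", "), call. = FALSE)
  ugpp_value * lut[[class_code]]
}

#' Annual GPP accumulation
#'
#' For each year, averages the daily-rate values over the pixel's valid
#' bimonthly periods and multiplies by 365 days (gC m-2 yr-1). Using the
#' valid rather than all six periods keeps high latitudes (polar-night
#' gaps) populated; the per-pixel valid count drives the mean. The annual
#' value is re-quantized at the cube's own scale, so a period-constant cube
#' annualizes exactly in stored precision.
#'
#' @param cube a bimonthly `gpp_cube`.
#' @return an annual `gpp_cube` (slice per year, units gC m-2 yr-1).
#' @export
annualize <- function(cube) {
  stopifnot(inherits(cube, "gpp_cube"), !is.null(cube$periods))
  years <- sort(unique(cube$periods$year))
  dm <- dim(cube$stored)
  out <- array(NA_integer_, c(dm[1], dm[2], length(years)))
  for (j in seq_along(years)) {
    idx <- which(cube$periods$year == years[j])
    block <- cube$stored[, , idx, drop = FALSE]
    nvalid <- apply(!is.na(block), c(1, 2), sum)
    msum <- apply(block, c(1, 2), function(v) sum(v, na.rm = TRUE))
    ann <- round(msum / nvalid * 365)  # stored-integer scale
    ann[nvalid == 0L] <- NA_real_
    storage.mode(ann) <- "integer"
    out[, , j] <- ann
  }
  gpp_cube(out, scale = cube$scale, years = years, grid = cube$grid,
           units = "gC m-2 yr-1")
}

#' Split a raster into tiles
#'
#' Partitions a raster into non-overlapping tiles of `tile_px` pixels
#' (ragged at the south/east edges), with deterministic ids
#' `x<col>_y<row>`. [mosaic_tiles()] reconstructs the input bit-exactly.
#' Production tiling is 1 degree x 1 degree in a geographic CRS; tests use
#' small pixel-aligned extents, which this pixel-block scheme covers.
#'
#' @param values matrix.
#' @param grid a [lue_grid()].
#' @param tile_px tile edge length in pixels.
#' @return list of tiles: each `list(id, row0, col0, values, grid)`.
#' @export
tile_raster <- function(values, grid, tile_px) {
  stopifnot(tile_px >= 1)
  tiles <- list()
  ty <- 0L
  for (r0 in seq(1L, nrow(values), by = tile_px)) {
    ty <- ty + 1L; tx <- 0L
    r1 <- min(r0 + tile_px - 1L, nrow(values))
    for (c0 in seq(1L, ncol(values), by = tile_px)) {
      tx <- tx + 1L
      c1 <- min(c0 + tile_px - 1L, ncol(values))
      tg <- lue_grid(c1 - c0 + 1L, r1 - r0 + 1L, grid$pixel_size,
                     origin = c(grid$origin[1] + (c0 - 1L) * grid$pixel_size,
                                grid$origin[2] - (r0 - 1L) * grid$pixel_size),
                     crs = grid$crs)
      tiles[[length(tiles) + 1L]] <-
        list(id = sprintf("x%03d_y%03d", tx, ty), row0 = r0, col0 = c0,
             values = values[r0:r1, c0:c1, drop = FALSE], grid = tg)
    }
  }
  tiles
}

#' Mosaic tiles back into one raster
#'
#' Disjoint paste of [tile_raster()] output; writing the same output pixel
#' twice is an error (tiles must not overlap).
#'
#' @param tiles list of tiles as produced by [tile_raster()].
#' @return the reconstructed matrix.
#' @export
mosaic_tiles <- function(tiles) {
  nr <- max(vapply(tiles, function(t) t$row0 + nrow(t$values) - 1L, numeric(1)))
  nc <- max(vapply(tiles, function(t) t$col0 + ncol(t$values) - 1L, numeric(1)))
  out <- matrix(vector(typeof(tiles[[1]]$values), 1)[NA], nr, nc)
  seen <- matrix(FALSE, nr, nc)
  for (t in tiles) {
    rr <- t$row0:(t$row0 + nrow(t$values) - 1L)
    cc <- t$col0:(t$col0 + ncol(t$values) - 1L)
    if (any(seen[rr, cc]))
      stop("overlapping tile writes at ", t$id, call. = FALSE)
    seen[rr, cc] <- TRUE
    out[rr, cc] <- t$values
  }
  out
}
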