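#' Raster grid descriptor
#'
#' A minimal georeferencing record for the in-memory rasters used throughout
#' the package: a regular north-up grid defined by its upper-left corner,
#' square pixel size and pixel counts. All rasters in a pipeline run share one
#' projected CRS; reprojection is out of scope.
#'
#' @param width,height pixel counts (columns, rows); must be >= 1.
#' @param pixel_size pixel edge length in CRS units (metres for projected
#'   grids); default 30.
#' @param origin numeric length-2, x/y of the grid's upper-left corner.
#' @param crs free-text CRS label carried into output metadata.
#' @return an object of class `lue_grid`.
#' @export
lue_grid <- function(width, height, pixel_size = 30,
                     origin = c(0, height * pixel_size),
                     crs = "local-projected") {
  stopifnot(width >= 1, height >= 1, pixel_size > 0, length(origin) == 2)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size = pixel_size, origin = as.numeric(origin), crs = crs),
    class = "lue_grid"
  )
}

#' @export
print.lue_grid <- function(x, ...) {
  cat(sprintf("<lue_grid> %d x %d px @ %g, origin (%g, %g), crs: %s\n",
              x$width, x$height, x$pixel_size, x$origin[1], x$origin[2],
              x$crs))
  invisible(x)
}

# x/y coordinates of pixel centers; rows run north -> south
grid_xcoords <- function(grid) {
  grid$origin[1] + (seq_len(grid$width) - 0.5) * grid$pixel_size
}

grid_ycoords <- function(grid) {
  grid$origin[2] - (seq_len(grid$height) - 0.5) * grid$pixel_size
}

grid_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + grid$width * grid$pixel_size,
    ymin = grid$origin[2] - grid$height * grid$pixel_size,
    ymax = grid$origin[2])
}

same_grid <- function(a, b, tol = 1e-9) {
  a$width == b$width && a$height == b$height &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

check_aligned <- function(...) {
  mats <- list(...)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) > 1L)
    stop("raster alignment error: shapes differ (", paste(dims, collapse = ", "),
         ")", call. = FALSE)
  invisible(TRUE)
}
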