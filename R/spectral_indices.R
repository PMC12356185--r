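#' Normalized difference vegetation index
#'
#' NDVI = (NIR - red) / (NIR + red). Missing inputs and zero denominators
#' propagate as NA; the output missing mask is exactly the union of the input
#' masks plus the zero-denominator pixels.
#'
#' @param red,nir aligned reflectance matrices/arrays (nominal \[0,1\]).
#' @return index values in \[-1, 1\] (NA where undefined).
#' @export
ndvi <- function(red, nir) {
  check_aligned(red, nir)
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Land surface water index
#'
#' LSWI = (NIR - SWIR1) / (NIR + SWIR1), a proxy for canopy/soil water
#' content. Same missing-value semantics as [ndvi()].
#'
#' @param nir,swir1 aligned reflectance matrices/arrays.
#' @return index values in \[-1, 1\] (NA where undefined).
#' @export
lswi <- function(nir, swir1) {
  check_aligned(nir, swir1)
  den <- nir + swir1
  out <- (nir - swir1) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' fAPAR stretch parameters
#'
#' The linear-stretch constants mapping NDVI to the fraction of absorbed
#' photosynthetically active radiation. The defaults are the 2% / 98% NDVI
#' distribution thresholds (0.03, 0.96) and the theoretical minimum and
#' maximum fAPAR for vegetation (0.001, 0.95).
#'
#' @param ndvi_min,ndvi_max NDVI stretch endpoints, `ndvi_min < ndvi_max`.
#' @param fapar_min,fapar_max fAPAR endpoints, `fapar_min < fapar_max`.
#' @return a named list classed `fapar_params`.
#' @export
fapar_params <- function(ndvi_min = 0.03, ndvi_max = 0.96,
                         fapar_min = 0.001, fapar_max = 0.95) {
  stopifnot(ndvi_min < ndvi_max, fapar_min < fapar_max)
  structure(list(ndvi_min = ndvi_min, ndvi_max = ndvi_max,
                 fapar_min = fapar_min, fapar_max = fapar_max),
            class = "fapar_params")
}

#' Fraction of absorbed PAR from NDVI
#'
#' Affine stretch of NDVI onto \[fapar_min, fapar_max\]:
#' `(ndvi - ndvi_min) * (fapar_max - fapar_min) / (ndvi_max - ndvi_min)
#'  + fapar_min`,
#' clamped to the fAPAR endpoints outside the NDVI stretch range (the
#' endpoints are theoretical extremes, so values beyond them are pinned
#' rather than extrapolated). NA propagates.
#'
#' @param x NDVI values (any numeric shape).
#' @param params a [fapar_params()] object.
#' @return fAPAR in \[fapar_min, fapar_max\].
#' @examples
#' fapar(0.96)  # 0.95
#' fapar(0.03)  # 0.001
#' @export
fapar <- function(x, params = fapar_params()) {
  stopifnot(inherits(params, "fapar_params"))
  out <- (x - params$ndvi_min) * (params$fapar_max - params$fapar_min) /
    (params$ndvi_max - params$ndvi_min) + params$fapar_min
  pmin(pmax(out, params$fapar_min), params$fapar_max)
}
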