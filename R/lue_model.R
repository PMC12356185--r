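#' Light-use-efficiency GPP model
#'
#' Constructs the forward model
#' `GPP = PAR x fAPAR x (eps_max x T_scalar x W_scalar)`
#' as a parameter object: the fAPAR stretch constants, the temperature
#' response constants, the water-scalar window/formula choices and the biome
#' maximum-LUE lookup table. [predict.lue_model()] runs the model on driver
#' cubes; the default maximum-LUE factor is 1 (uncalibrated GPP, with biome
#' calibration deferred to metadata).
#'
#' @param fapar a [fapar_params()] object.
#' @param temperature a [temp_params()] object.
#' @param wscalar_window window for the per-pixel LSWI maximum:
#'   `"annual"` (default), `"bimonthly"` or `"full-series"`.
#' @param wscalar_formula `"printed"` (default) or `"vpm"`; see [w_scalar()].
#' @param lut a [biome_lut()].
#' @return an object of class `lue_model`.
#' @examples
#' m <- lue_model()
#' coef(m)
#' @export
lue_model <- function(fapar = fapar_params(), temperature = temp_params(),
                      wscalar_window = c("annual", "bimonthly", "full-series"),
                      wscalar_formula = c("printed", "vpm"),
                      lut = biome_lut()) {
  structure(list(fapar = fapar, temperature = temperature,
                 wscalar_window = match.arg(wscalar_window),
                 wscalar_formula = match.arg(wscalar_formula),
                 lut = lut),
            class = "lue_model")
}

#' @export
print.lue_model <- function(x, ...) {
  cat("Light-use-efficiency GPP model\n")
  cat(sprintf("  fAPAR stretch: NDVI [%g, %g] -> fAPAR [%g, %g]\n",
              x$fapar$ndvi_min, x$fapar$ndvi_max,
              x$fapar$fapar_min, x$fapar$fapar_max))
  cat(sprintf("  temperature response: Tmin %g, Topt %g, Tmax %g degC\n",
              x$temperature$t_min, x$temperature$t_opt, x$temperature$t_max))
  cat(sprintf("  water scalar: %s formula, %s LSWI_max window\n",
              x$wscalar_formula, x$wscalar_window))
  cat(sprintf("  biome LUT: %d classes (GRA = %g gC m-2 d-1 MJ-1)\n",
              length(x$lut), x$lut[["GRA"]]))
  invisible(x)
}

#' @export
coef.lue_model <- function(object, ...) {
  c(ndvi_min = object$fapar$ndvi_min, ndvi_max = object$fapar$ndvi_max,
    fapar_min = object$fapar$fapar_min, fapar_max = object$fapar$fapar_max,
    t_min = object$temperature$t_min, t_opt = object$temperature$t_opt,
    t_max = object$temperature$t_max)
}

#' Run the LUE model on driver cubes
#'
#' Computes NDVI, fAPAR, LSWI, the per-pixel LSWI window maximum and the
#' temperature and water scalars, then the bimonthly uncalibrated GPP
#' (maximum LUE = 1), quantized at storage step 0.1 into a [gpp_cube()].
#' A pixel missing in any driver band is missing in the output.
#'
#' @param object a [lue_model()].
#' @param reflectance a `refl_cube` (red/NIR/SWIR1 bimonthly stacks).
#' @param climate a `climate_cube` on the same grid/periods
#'   (see [prepare_climate()]).
#' @param type `"cube"` (quantized `gpp_cube`, default) or `"real"` (the
#'   unquantized array, for diagnostics).
#' @param ... unused.
#' @return a `gpp_cube` (scale 0.1) or a real-valued array.
#' @export
predict.lue_model <- function(object, reflectance, climate,
                              type = c("cube", "real"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(reflectance, "refl_cube"),
            identical(dim(reflectance$red), dim(climate$lst)),
            identical(reflectance$periods$year, climate$periods$year),
            identical(reflectance$periods$period, climate$periods$period))
  nd <- ndvi(reflectance$red, reflectance$nir)
  fp <- fapar(nd, object$fapar)
  lw <- lswi(reflectance$nir, reflectance$swir1)
  lwm <- lswi_max(lw, periods = reflectance$periods,
                  window = object$wscalar_window)
  ts <- t_scalar(climate$lst, object$temperature)
  ws <- w_scalar(lw, lwm, formula = object$wscalar_formula)
  g <- ugpp(climate$par, fp, ts, ws)
  if (type == "real") return(g)
  quantize(g, step = 0.1, periods = reflectance$periods,
           grid = reflectance$grid)
}
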