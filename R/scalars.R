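#' Temperature response parameters
#'
#' Minimum, maximum and optimal temperatures for photosynthesis (degrees
#' Celsius) used by the temperature down-regulation scalar. The defaults
#' (0.0, 48.0, 20.3) are globally adjusted values for the
#' vegetation-photosynthesis family of LUE models.
#'
#' @param t_min,t_max,t_opt degrees C with `t_min < t_opt < t_max`.
#' @return a named list classed `temp_params`.
#' @export
temp_params <- function(t_min = 0.0, t_max = 48.0, t_opt = 20.3) {
  stopifnot(t_min < t_opt, t_opt < t_max)
  structure(list(t_min = t_min, t_max = t_max, t_opt = t_opt),
            class = "temp_params")
}

#' Temperature down-regulation scalar
#'
#' For a bimonthly mean temperature T (degrees C):
#' `(T - t_max)(T - t_min) / [(T - t_max)(T - t_min) - (T - t_opt)^2]`,
#' with the value forced to 0 for T <= t_min (zero or negative temperatures
#' shut photosynthesis down in this formulation) and for T >= t_max, where
#' the quadratic rationale no longer applies and 0 extends the curve
#' continuously. The result is clamped to \[0, 1\]; non-finite temperatures
#' give NA.
#'
#' @param t temperature(s), degrees C; any numeric shape.
#' @param params a [temp_params()] object.
#' @return scalar values in \[0, 1\] with NA propagation.
#' @examples
#' t_scalar(20.3)  # 1
#' t_scalar(-5)    # 0
#' @export
t_scalar <- function(t, params = temp_params()) {
  stopifnot(inherits(params, "temp_params"))
  num <- (t - params$t_max) * (t - params$t_min)
  den <- num - (t - params$t_opt)^2
  out <- num / den
  out[!is.na(t) & (t <= params$t_min | t >= params$t_max)] <- 0
  out[!is.finite(t)] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Per-pixel maximum LSWI over a window
#'
#' The water scalar references each pixel's maximum LSWI over a window of
#' bimonthly composites. The sentence "maximum LSWI in a bimonthly period"
#' cannot be executed on a single composite (one value per pixel), so the
#' default window is the calendar year, the convention of the
#' vegetation-photosynthesis model family; "bimonthly" (identity) and
#' "full-series" windows are selectable.
#'
#' @param lswi_series 3-D array \[rows, cols, periods\] of LSWI composites.
#' @param periods data.frame with `year`, `period` per slice (required for
#'   the annual window); defaults to all slices in one year.
#' @param window one of "annual", "bimonthly", "full-series".
#' @return array of the same shape: per-slice applicable LSWI_max (NA where
#'   the window holds no valid observation).
#' @export
lswi_max <- function(lswi_series,
                     periods = NULL,
                     window = c("annual", "bimonthly", "full-series")) {
  window <- match.arg(window)
  stopifnot(length(dim(lswi_series)) == 3L)
  np <- dim(lswi_series)[3]
  if (window == "bimonthly") return(lswi_series)
  if (is.null(periods))
    periods <- data.frame(year = rep(0L, np), period = seq_len(np))
  stopifnot(nrow(periods) == np)
  grp <- if (window == "annual") periods$year else rep(0L, np)
  out <- lswi_series
  for (g in unique(grp)) {
    idx <- which(grp == g)
    block <- lswi_series[, , idx, drop = FALSE]
    mx <- apply(block, c(1, 2), function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    for (i in idx) out[, , i] <- mx
  }
  out
}

#' Water down-regulation scalar
#'
#' Printed form (default): `1 - (1 - LSWI) / (1 + LSWI_max)`. The common
#' alternative `(1 + LSWI) / (1 + LSWI_max)` is available as
#' `formula = "vpm"` for sensitivity checks. Values are clamped to \[0, 1\];
#' pixels where `1 + LSWI_max <= 0` are NA (undefined denominator).
#'
#' @param lswi LSWI values.
#' @param lswi_max matching per-pixel window maxima (see [lswi_max()]).
#' @param formula `"printed"` or `"vpm"`.
#' @return scalar values in \[0, 1\] with NA propagation.
#' @examples
#' w_scalar(0.2, 0.5)  # 1 - 0.8/1.5 = 0.4667
#' w_scalar(1, 0.3)    # 1
#' @export
w_scalar <- function(lswi, lswi_max, formula = c("printed", "vpm")) {
  formula <- match.arg(formula)
  den <- 1 + lswi_max
  out <- if (formula == "printed") 1 - (1 - lswi) / den else (1 + lswi) / den
  out[!is.na(den) & den <= 0] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Effective light-use efficiency
#'
#' Down-regulates the biome's theoretical maximum LUE by the temperature and
#' water scalars: `eps_max * ts * ws` (gC m-2 d-1 MJ-1).
#'
#' @param eps_max theoretical maximum LUE, > 0.
#' @param ts,ws scalars in \[0, 1\].
#' @return effective LUE, never exceeding `eps_max`.
#' @export
eps_lue <- function(eps_max, ts, ws) {
  stopifnot(all(eps_max > 0, na.rm = TRUE))
  eps_max * ts * ws
}
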