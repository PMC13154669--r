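#' Non-baffled shake-flask specification
#'
#' Parameters of the power-law correlation for the maximum oxygen transfer
#' rate of non-baffled Erlenmeyer flasks. The shaking-frequency exponent is
#' `1.18 - osmolarity / 10.1`; the default osmolarity 0.505 osmol/L makes
#' it 1.13, the value for LB-type media.
#'
#' @param osmolarity Medium osmolarity (osmol/L).
#' @param rpm Shaking frequency (rpm).
#' @param filling_volume_mL Filling volume V_L (mL).
#' @param shaking_diameter_mm Orbital shaking diameter d0 (mm).
#' @param flask_diameter_mm Flask (bottom) diameter d (mm).
#' @param pressure_bar Absolute pressure (bar).
#' @param y_o2 O2 mole fraction of the gas phase.
#' @return A `flask_spec_nb` list.
#' @export
flask_nb <- function(osmolarity = 0.505, rpm = 250, filling_volume_mL = 100,
                     shaking_diameter_mm = 50, flask_diameter_mm = 108,
                     pressure_bar = 1.013, y_o2 = 0.2093) {
  vals <- c(osmolarity, rpm, filling_volume_mL, shaking_diameter_mm,
            flask_diameter_mm, pressure_bar, y_o2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all flask parameters must be positive")
  if (y_o2 >= 1) stopf("y_o2 must be in (0, 1)")
  structure(list(osmolarity = osmolarity, rpm = rpm,
                 filling_volume_mL = filling_volume_mL,
                 shaking_diameter_mm = shaking_diameter_mm,
                 flask_diameter_mm = flask_diameter_mm,
                 pressure_bar = pressure_bar, y_o2 = y_o2),
            class = "flask_spec_nb")
}

#' Baffled shake-flask specification
#'
#' Coefficients of the Gaussian correlation for the maximum oxygen transfer
#' rate of bottom-baffled 500 mL sensor flasks, together with the oxygen
#' solubility. Defaults are the published coefficients for this flask
#' geometry at 20% filling; `volume_mL` is interpreted as the filling
#' volume paired with `y0`.
#'
#' @param c_star_mmol_L O2 solubility (mmol/L) at cultivation temperature.
#' @param a,b,c,x0,y0 Correlation coefficients.
#' @param rpm Shaking frequency (rpm).
#' @param volume_mL Filling volume term (mL).
#' @return A `flask_spec_bf` list.
#' @export
flask_bf <- function(c_star_mmol_L = 0.21, a = 333.95, b = 59.23,
                     c = 347.81, x0 = 235.32, y0 = 276.87,
                     rpm = 250, volume_mL = 100) {
  if (b <= 0 || c <= 0) stopf("b and c must be positive")
  structure(list(c_star_mmol_L = c_star_mmol_L, a = a, b = b, c = c,
                 x0 = x0, y0 = y0, rpm = rpm, volume_mL = volume_mL),
            class = "flask_spec_bf")
}

#' Maximum OTR of a non-baffled flask (power-law correlation)
#'
#' `OTRmax = 3.72e-7 * Osmol^0.05 * n^(1.18 - Osmol/10.1) * V_L^-0.74 *
#' d0^0.33 * d^1.88 * p_R * y_O2`. The correlation's absolute scale
#' depends on the unit system of the source correlation, which is not
#' fixed by the symbols alone; `calibration` is a documented multiplicative
#' constant (default 1) for anchoring absolute values against a reference
#' configuration. Ratios between configurations, and the monotone
#' dependence on `rpm` (increasing) and filling volume (decreasing), are
#' calibration-free.
#'
#' @param spec A [flask_nb()] specification.
#' @param calibration Multiplicative calibration constant.
#' @return OTRmax in mmol/(L h) times the calibration constant.
#' @export
otr_max_unbaffled <- function(spec, calibration = 1) {
  stopifnot(inherits(spec, "flask_spec_nb"))
  calibration * 3.72e-7 * spec$osmolarity^0.05 *
    spec$rpm^(1.18 - spec$osmolarity / 10.1) *
    spec$filling_volume_mL^-0.74 *
    spec$shaking_diameter_mm^0.33 *
    spec$flask_diameter_mm^1.88 *
    spec$pressure_bar * spec$y_o2
}

#' Maximum OTR of a baffled flask (Gaussian correlation)
#'
#' `OTRmax = c_star * a * exp(-0.5 * (((n - x0)/b)^2 + ((V - y0)/c)^2))`.
#' The peak value is `c_star * a` (70.13 mmol/(L h) with the default
#' coefficients). OTR ratios between two shaking frequencies at the same
#' volume are independent of `c_star` and `a`.
#'
#' @param spec A [flask_bf()] specification.
#' @return OTRmax in mmol/(L h).
#' @export
otr_max_baffled <- function(spec) {
  stopifnot(inherits(spec, "flask_spec_bf"))
  spec$c_star_mmol_L * spec$a *
    exp(-0.5 * (((spec$rpm - spec$x0) / spec$b)^2 +
                ((spec$volume_mL - spec$y0) / spec$c)^2))
}

#' OTRmax over a grid of shaking frequencies and volumes
#'
#' @param rpm Numeric vector of shaking frequencies.
#' @param volume_mL Numeric vector of filling volumes.
#' @param flask `"bf"` (baffled Gaussian correlation) or `"nb"`
#'   (non-baffled power law).
#' @param ... Additional arguments to [flask_bf()] / [flask_nb()].
#' @return Tibble with columns `rpm`, `volume_mL`, `otr_max`.
#' @export
otr_grid <- function(rpm, volume_mL = 100, flask = c("bf", "nb"), ...) {
  flask <- match.arg(flask)
  grid <- tidyr::expand_grid(rpm = rpm, volume_mL = volume_mL)
  grid$otr_max <- purrr::map2_dbl(grid$rpm, grid$volume_mL, function(n, v) {
    if (flask == "bf") otr_max_baffled(flask_bf(rpm = n, volume_mL = v, ...))
    else otr_max_unbaffled(flask_nb(rpm = n, filling_volume_mL = v, ...))
  })
  grid
}

#' Growth-kinetics parameters from a cultivation time series
#'
#' Estimates, over a user-specified time window: the specific growth rate
#' `mu` as the ordinary least-squares slope of `ln(CDW)` versus time; per
#' substrate the volumetric consumption rate `r_S` as minus the OLS slope
#' of concentration versus time and the biomass-specific rate
#' `q_S = r_S / mean(CDW)`; and the biomass yield
#' `Y_XS = delta CDW / (-delta glucose)` from the window endpoints. The
#' yield refers to consumed glucose only, so values above 0.5 are possible
#' when a second substrate is co-consumed.
#'
#' @param timeseries Data frame with a time column `t_h` (hours), a biomass
#'   column `CDW_gL` (g/L), and one concentration column per substrate
#'   (g/L).
#' @param window Numeric `c(t_start, t_end)` in hours; only points inside
#'   (inclusive) are used. Defaults to the full data range.
#' @param substrates Names of the substrate columns (default: every column
#'   other than `t_h` and `CDW_gL`).
#' @param yield_substrate Substrate used for the biomass yield (default
#'   `"glucose_gL"` if present, else the first substrate).
#' @return An object of class `kinetics_fit` with fields `mu_h`,
#'   `substrates` (tibble: `substrate`, `r_S_gLh`, `q_S_ggh`), `Y_XS_gg`,
#'   `window`, `n_points`.
#' @export
fit_kinetics <- function(timeseries, window = NULL, substrates = NULL,
                         yield_substrate = NULL) {
  ts <- tibble::as_tibble(timeseries)
  if (!all(c("t_h", "CDW_gL") %in% names(ts)))
    stopf("time series needs columns `t_h` and `CDW_gL`")
  if (is.null(window)) window <- range(ts$t_h)
  if (window[1] > window[2]) stopf("invalid window")
  sel <- ts$t_h >= window[1] & ts$t_h <= window[2]
  ts <- ts[sel, , drop = FALSE]
  if (nrow(ts) < 3) stopf("need >= 3 points inside the window")
  if (any(ts$CDW_gL <= 0))
    stopf("nonpositive CDW inside the window; cannot take logarithms")
  if (is.null(substrates))
    substrates <- setdiff(names(ts), c("t_h", "CDW_gL"))
  if (is.null(yield_substrate))
    yield_substrate <- if ("glucose_gL" %in% substrates) "glucose_gL"
      else substrates[1]

  mu <- unname(coef(lm(log(ts$CDW_gL) ~ ts$t_h))[2])
  mean_cdw <- mean(ts$CDW_gL)
  subs <- dplyr::bind_rows(lapply(substrates, function(s) {
    r_s <- -unname(coef(lm(ts[[s]] ~ ts$t_h))[2])
    tibble::tibble(substrate = s, r_S_gLh = r_s, q_S_ggh = r_s / mean_cdw)
  }))
  y_xs <- NA_real_
  if (length(yield_substrate) && yield_substrate %in% names(ts)) {
    dS <- ts[[yield_substrate]][which.max(ts$t_h)] -
      ts[[yield_substrate]][which.min(ts$t_h)]
    dX <- ts$CDW_gL[which.max(ts$t_h)] - ts$CDW_gL[which.min(ts$t_h)]
    if (abs(dS) > .Machine$double.eps^0.5) y_xs <- dX / (-dS)
  }
  structure(list(mu_h = mu, substrates = subs, Y_XS_gg = y_xs,
                 yield_substrate = yield_substrate,
                 window = window, n_points = nrow(ts)),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit: mu = %.3f 1/h, window %g-%g h, n = %d>\n",
              x$mu_h, x$window[1], x$window[2], x$n_points))
  print(x$substrates)
  cat(sprintf("Y_X/S (%s): %s g/g\n", x$yield_substrate,
              format(x$Y_XS_gg, digits = 3)))
  invisible(x)
}

#' Tidy a kinetics fit into one row per estimated parameter
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `unit`.
#' @method tidy kinetics_fit
#' @export
tidy.kinetics_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "mu", estimate = x$mu_h, unit = "1/h"),
    tibble::tibble(term = paste0("r_S[", x$substrates$substrate, "]"),
                   estimate = x$substrates$r_S_gLh, unit = "g/(L h)"),
    tibble::tibble(term = paste0("q_S[", x$substrates$substrate, "]"),
                   estimate = x$substrates$q_S_ggh, unit = "g/(g h)"),
    tibble::tibble(term = "Y_XS", estimate = x$Y_XS_gg, unit = "g/g")
  )
}

#' One-row summary of a kinetics fit
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance kinetics_fit
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(mu_h = x$mu_h, Y_XS_gg = x$Y_XS_gg,
                 t_start = x$window[1], t_end = x$window[2],
                 n_points = x$n_points)
}
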