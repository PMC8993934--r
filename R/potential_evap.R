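#' Priestley-Taylor potential evaporation
#'
#' Daily potential evaporation `E_p = alpha * Delta/(Delta + gamma) * Rn`,
#' converted from W/m2 to mm/day through the latent heat of vaporisation.
#' The slope of the saturation vapour pressure curve `Delta` and the
#' psychrometric constant `gamma` follow the standard FAO-56 closed forms;
#' the latent heat is taken as weakly temperature dependent,
#' `lambda = 2.501 - 0.002361 Ta` MJ/kg. Ground heat flux is neglected at
#' the daily scale. Negative net radiation floors the result at zero.
#'
#' @param Rn net radiation, W/m2 (vectorised).
#' @param Ta air temperature, degC (vectorised); must lie in (-60, 60).
#' @param alpha Priestley-Taylor coefficient (default 1.26).
#' @param pressure surface air pressure, kPa (default 101.3).
#'
#' @return potential evaporation, mm/day, never negative.
#' @export
#' @examples
#' priestley_taylor(Rn = 100, Ta = 20) # about 3 mm/day
priestley_taylor <- function(Rn, Ta, alpha = 1.26, pressure = 101.3) {
  if (any(!is.finite(Ta)) || any(Ta <= -60) || any(Ta >= 60)) {
    stop_arg("Ta must be finite and within (-60, 60) degC")
  }
  check_number(alpha, "alpha", lo = 0)
  es <- 0.6108 * exp(17.27 * Ta / (Ta + 237.3))         # kPa
  delta <- 4098 * es / (Ta + 237.3)^2                   # kPa/degC
  gamma <- 0.000665 * pressure                          # kPa/degC
  lambda <- 2.501 - 0.002361 * Ta                       # MJ/kg
  rn_mj <- pmax(0, Rn) * 0.0864                         # W/m2 -> MJ/m2/day
  pmax(0, alpha * delta / (delta + gamma) * rn_mj / lambda)
}

#' Flag rain days and days following rain
#'
#' A rain day has precipitation above `threshold` (mm/day). A post-rain day
#' is a dry day immediately following one or more rain days; these are the
#' days on which ecosystems are assumed to transpire at their potential,
#' used to anchor the potential-transpiration bias correction.
#'
#' @param P precipitation series, mm/day.
#' @param threshold rain-day threshold, mm/day (default 0.5).
#' @return a list with logical vectors `rain_day` and `post_rain`.
#' @export
rain_flags <- function(P, threshold = 0.5) {
  if (any(!is.finite(P)) || any(P < 0)) stop_arg("P must be finite and >= 0")
  rain <- P > threshold
  post <- c(FALSE, rain[-length(rain)]) & !rain
  list(rain_day = rain, post_rain = post)
}

#' Bias-correct a raw potential-transpiration series against observed fluxes
#'
#' Affine rescaling that maps the raw potential transpiration onto the
#' moments of the observed transpiration flux, with the moments estimated on
#' a reference subset (by default the days following rain, where
#' transpiration is assumed to run at its potential):
#' `scaled = (raw - mean_raw) / sd_raw * sd_flux + mean_flux`.
#' The affine map is fit on the subset and applied to the full series, so on
#' the subset the scaled series reproduces the observed mean and sd exactly.
#'
#' @param ept_raw raw potential transpiration series, mm/day.
#' @param et_flux observed transpiration series, mm/day (same length).
#' @param subset logical mask selecting the reference days (e.g. the
#'   `post_rain` flags from [rain_flags()]); `NULL` uses the full series.
#' @param sample_sd use the sample (n-1) standard deviation (default) or the
#'   population form.
#'
#' @return the scaled series, mm/day (same length as `ept_raw`).
#' @export
#' @examples
#' scale_ept(c(2, 4, 6), c(2, 3, 4)) # c(2, 3, 4)
scale_ept <- function(ept_raw, et_flux, subset = NULL, sample_sd = TRUE) {
  if (length(ept_raw) != length(et_flux)) {
    stop_arg("ept_raw and et_flux must have equal length")
  }
  if (is.null(subset)) subset <- rep(TRUE, length(ept_raw))
  if (sum(subset) < 2L) {
    stop_arg("reference subset must contain at least 2 days")
  }
  raw_s <- ept_raw[subset]
  flx_s <- et_flux[subset]
  denom <- if (sample_sd) sum(subset) - 1 else sum(subset)
  sd_raw <- sqrt(sum((raw_s - mean(raw_s))^2) / denom)
  sd_flx <- sqrt(sum((flx_s - mean(flx_s))^2) / denom)
  if (sd_raw <= 0) {
    stop_arg("raw potential transpiration has zero variance on the subset")
  }
  (ept_raw - mean(raw_s)) / sd_raw * sd_flx + mean(flx_s)
}

#' Simplified canopy interception loss
#'
#' Threshold stand-in for an analytical interception model: the canopy
#' evaporates at most `c_canopy * LAI` mm of a day's rainfall,
#' `E_i = min(P, c_canopy * LAI)`. Dry days yield zero.
#'
#' @param P precipitation, mm/day (vectorised).
#' @param LAI leaf area index, m2/m2.
#' @param c_canopy interception capacity per unit LAI, mm/day (default 0.5).
#' @return interception loss, mm/day.
#' @export
#' @examples
#' interception_simple(10, 4, 0.5) # 2
interception_simple <- function(P, LAI, c_canopy = 0.5) {
  if (any(!is.finite(P)) || any(P < 0)) stop_arg("P must be finite and >= 0")
  if (any(!is.finite(LAI)) || any(LAI < 0)) {
    stop_arg("LAI must be finite and >= 0")
  }
  pmin(P, c_canopy * LAI)
}
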