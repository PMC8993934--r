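#' Process-based transpiration stress
#'
#' The classic semi-empirical transpiration stress factor combining
#' phenological state (vegetation optical depth, VOD) and root-zone water
#' availability:
#' `S_t = sqrt(VOD / VOD_max) * (1 - ((w_c - w_w) / (w_c - w_wp))^2)`.
#' Inputs are clamped before evaluation (`VOD <= VOD_max`,
#' `w_wp <= w_w <= w_c`) so the result is bounded to \[0, 1\]; moisture above
#' the critical level means no water limitation and moisture below wilting
#' point means full stress.
#'
#' @param VOD vegetation optical depth (vectorised, dimensionless, >= 0).
#' @param w_w volumetric moisture of the wettest soil layer (vectorised).
#' @param params a [soil_params()] object (supplies `w_c`, `w_wp`).
#' @param vod_max upper VOD reference, typically from [compute_vodmax()].
#'
#' @return S_t in \[0, 1\].
#' @export
#' @examples
#' p <- soil_params("short", w_wp = 0.1, w_c = 0.3)
#' process_st(VOD = 0.81, w_w = 0.25, params = p, vod_max = 1) # 0.84375
process_st <- function(VOD, w_w, params, vod_max) {
  check_number(vod_max, "vod_max")
  if (vod_max <= 0) stop_arg("vod_max must be positive")
  if (any(!is.finite(VOD)) || any(VOD < 0)) {
    stop_arg("VOD must be finite and >= 0")
  }
  denom <- params$w_c - params$w_wp
  if (denom <= 0) stop_arg("w_c must exceed w_wp")
  vod_r <- pmin(VOD, vod_max) / vod_max
  w <- clamp(w_w, params$w_wp, params$w_c)
  sqrt(vod_r) * (1 - ((params$w_c - w) / denom)^2)
}

#' Process-based bare-soil evaporation stress
#'
#' Linear reduction of soil evaporation with drying of the surface layer:
#' `S_b = 1 - (w_c - w_1) / (w_c - w_r)`, clamped to \[0, 1\].
#'
#' @param w_1 volumetric moisture of the surface soil layer (vectorised).
#' @param params a [soil_params()] object (supplies `w_c`, `w_r`).
#' @return S_b in \[0, 1\].
#' @export
#' @examples
#' p <- soil_params("short", w_r = 0.05, w_c = 0.3)
#' process_sb(0.175, p) # 0.5
process_sb <- function(w_1, params) {
  denom <- params$w_c - params$w_r
  if (denom <= 0) stop_arg("w_c must exceed w_r")
  clamp01(1 - (params$w_c - w_1) / denom)
}

#' Upper reference VOD as the 99th percentile of a series
#'
#' Uses the linear-interpolation percentile convention (R's default,
#' `quantile(type = 7)`); the convention matters for short series and is
#' fixed here so the stress factor is reproducible.
#'
#' @param vod_series vegetation optical depth series (non-empty).
#' @param prob percentile (default 0.99).
#' @return the percentile value.
#' @export
#' @examples
#' compute_vodmax(1:100) # 99.01
compute_vodmax <- function(vod_series, prob = 0.99) {
  vod_series <- vod_series[is.finite(vod_series)]
  if (length(vod_series) == 0L) stop_arg("vod_series must be non-empty")
  unname(stats::quantile(vod_series, probs = prob, type = 7))
}
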