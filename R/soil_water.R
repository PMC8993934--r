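#' Soil parameter set for the multi-layer water balance
#'
#' Bundles the hydraulic constants used by the running water balance and the
#' stress formulations. Tall vegetation uses three soil layers, short
#' vegetation two, bare soil a single surface layer. Default layer depths and
#' moisture constants are generic loam placeholders; the host model this
#' design mirrors takes them from soil maps.
#'
#' @param veg_class one of `"tall"`, `"short"`, `"bare"`; sets the default
#'   number of layers.
#' @param depths layer depths in mm, top first. Defaults: 100/900/1500 mm
#'   (tall), 100/900 mm (short), 100 mm (bare).
#' @param w_wp wilting point, volumetric (m3/m3).
#' @param w_c critical soil moisture, volumetric; transpiration is
#'   unrestricted by soil water above this level.
#' @param w_r residual soil moisture, volumetric; water below this level is
#'   not extractable.
#' @param porosity saturation moisture content, volumetric.
#'
#' @return An object of class `soil_params`.
#' @export
#' @examples
#' p <- soil_params("tall")
#' compute_paw(0.2, p)
soil_params <- function(veg_class = c("tall", "short", "bare"),
                        depths = NULL,
                        w_wp = 0.15, w_c = 0.30, w_r = 0.05,
                        porosity = 0.45) {
  veg_class <- match.arg(veg_class)
  if (is.null(depths)) {
    depths <- switch(veg_class,
                     tall  = c(100, 900, 1500),
                     short = c(100, 900),
                     bare  = 100)
  }
  if (any(!is.finite(depths)) || any(depths <= 0)) {
    stop_arg("layer depths must be positive")
  }
  if (!(w_r < w_wp && w_wp < w_c && w_c < porosity)) {
    stop_arg("soil moisture constants must satisfy w_r < w_wp < w_c < porosity")
  }
  structure(list(veg_class = veg_class, depths = as.numeric(depths),
                 n_layers = length(depths),
                 w_wp = w_wp, w_c = w_c, w_r = w_r, porosity = porosity),
            class = "soil_params")
}

#' Initialise a soil moisture state
#'
#' @param params a [soil_params()] object.
#' @param w initial volumetric moisture, recycled across layers; defaults to
#'   the critical moisture (unstressed start).
#'
#' @return An object of class `soil_state` with fields `w` (per-layer
#'   volumetric moisture), `w_1` (surface layer), `w_w` (wettest layer) and
#'   `paw` (plant-available water fraction).
#' @export
soil_state_init <- function(params, w = params$w_c) {
  w <- rep_len(as.numeric(w), params$n_layers)
  if (any(w < params$w_r) || any(w > params$porosity)) {
    stop_arg("initial moisture outside [w_r, porosity]")
  }
  new_soil_state(w, params)
}

new_soil_state <- function(w, params) {
  structure(list(w = w,
                 w_1 = w[1L],
                 w_w = max(w),
                 paw = compute_paw(max(w), params)),
            class = "soil_state")
}

#' Total column storage in mm
#' @param state a `soil_state`.
#' @param params the matching [soil_params()].
#' @return storage in mm.
#' @export
soil_storage <- function(state, params) {
  sum(state$w * params$depths)
}

#' Plant-available water fraction
#'
#' PAW scales the wettest-layer moisture between wilting point and critical
#' moisture, `(w_w - w_wp) / (w_c - w_wp)`, and is clamped to \[0, 1\]:
#' moisture above the critical level implies no water limitation.
#'
#' @param w_w volumetric moisture of the wettest layer (vectorised).
#' @param params a [soil_params()] object.
#' @return PAW in \[0, 1\].
#' @export
#' @examples
#' compute_paw(0.2, soil_params("short", w_wp = 0.1, w_c = 0.3)) # 0.5
compute_paw <- function(w_w, params) {
  denom <- params$w_c - params$w_wp
  if (!is.finite(denom) || denom <= 0) {
    stop_arg("w_c must exceed w_wp")
  }
  clamp01((w_w - params$w_wp) / denom)
}

#' Advance the soil water balance by one day
#'
#' Tipping-bucket scheme: net precipitation infiltrates the surface layer;
#' bare-soil evaporation is extracted from the surface layer and
#' transpiration from the wettest layer (both capped so no layer is drawn
#' below residual moisture); moisture above porosity cascades to the layer
#' below, and saturation excess in the bottom layer leaves the column as
#' drainage. Mass is conserved exactly:
#' `storage_change = P - E_extracted - drainage`.
#'
#' @param state a `soil_state`.
#' @param P net water input at the soil surface, mm/day (throughfall).
#' @param E_t transpiration demand, mm/day (from the wettest layer).
#' @param E_b soil evaporation demand, mm/day (from the surface layer).
#' @param params a [soil_params()] object.
#'
#' @return A list: `state` (updated `soil_state`), `drainage` (mm/day),
#'   `E_t` and `E_b` actually extracted (mm/day), and `shortfall` (demanded
#'   minus extracted, mm/day).
#' @export
step_water_balance <- function(state, P, E_t = 0, E_b = 0, params) {
  check_number(P, "P", lo = 0)
  check_number(E_t, "E_t", lo = 0)
  check_number(E_b, "E_b", lo = 0)
  w <- state$w
  d <- params$depths
  n <- params$n_layers

  ## transpiration is drawn from the layer that was wettest at the start of
  ## the day (the same state the stress factor was computed from)
  iw <- which.max(w)

  ## infiltration into surface layer
  w[1L] <- w[1L] + P / d[1L]

  ## extraction: E_b from layer 1, E_t from the start-of-day wettest layer
  avail_b <- max(0, (w[1L] - params$w_r) * d[1L])
  e_b_act <- min(E_b, avail_b)
  w[1L] <- w[1L] - e_b_act / d[1L]
  avail_t <- max(0, (w[iw] - params$w_r) * d[iw])
  e_t_act <- min(E_t, avail_t)
  w[iw] <- w[iw] - e_t_act / d[iw]

  ## cascade saturation excess downwards; bottom excess drains out
  drainage <- 0
  for (l in seq_len(n)) {
    excess <- max(0, (w[l] - params$porosity) * d[l])
    if (excess > 0) {
      w[l] <- params$porosity
      if (l < n) {
        w[l + 1L] <- w[l + 1L] + excess / d[l + 1L]
      } else {
        drainage <- drainage + excess
      }
    }
  }

  list(state = new_soil_state(w, params),
       drainage = drainage,
       E_t = e_t_act,
       E_b = e_b_act,
       shortfall = (E_t - e_t_act) + (E_b - e_b_act))
}

#' Dump a soil state to a one-row data frame (debugging aid)
#' @param state a `soil_state`.
#' @return a data frame with one column per layer plus `w_1`, `w_w`, `paw`.
#' @export
soil_state_as_df <- function(state) {
  out <- as.data.frame(as.list(stats::setNames(
    state$w, paste0("w", seq_along(state$w)))))
  out$w_1 <- state$w_1
  out$w_w <- state$w_w
  out$paw <- state$paw
  out
}
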