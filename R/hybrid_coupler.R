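#' Runtime parameters of the coupled model
#'
#' @param vod_max upper reference VOD for the process stress formula.
#' @param alpha Priestley-Taylor coefficient.
#' @param c_canopy interception capacity per unit LAI, mm/day.
#' @param rain_threshold rain-day threshold, mm/day.
#' @param use_interception toggle the interception component.
#' @param e_w open-water evaporation, mm/day (constant stub, default 0).
#' @param e_s snow sublimation, mm/day (constant stub, default 0).
#' @return a list of class `run_params`.
#' @export
run_params <- function(vod_max = 1, alpha = 1.26, c_canopy = 0.5,
                       rain_threshold = 0.5, use_interception = TRUE,
                       e_w = 0, e_s = 0) {
  structure(as.list(environment()), class = "run_params")
}

## anomaly of one driver against a pre-computed climatology (0 if absent)
clim_anomaly <- function(clim, var, value, doy) {
  if (is.null(clim) || is.null(clim[[var]])) return(0)
  value - clim[[var]][doy]
}

#' Advance the coupled model by one day
#'
#' One pass of the bidirectional loop: the start-of-day soil state yields
#' plant-available water; the covariate vector (absolutes plus anomalies
#' against a pre-computed climatology) is handed to the stress predictor;
#' the resulting stress factors scale the Priestley-Taylor potential into
#' evaporation components (stress applied to the potential before
#' land-cover-fraction weighting); and the extracted water updates each
#' fraction's soil column for the next day. Pure function of its inputs.
#'
#' @param forcing one-row forcing (list or single-row data frame with `P`,
#'   `Rn`, `Ta`, `VPD`, `SWi`, `VOD`, `CO2`, `LAI`, `date`).
#' @param soils named list of `soil_state` columns (subset of `tall`,
#'   `short`, `bare`).
#' @param models named list of stress predictors for `tall` and `short`
#'   (objects accepted by [predict_stress()]).
#' @param site a [site_meta()] with the land-cover fractions.
#' @param soil_par named list of [soil_params()] matching `soils`.
#' @param params a [run_params()].
#' @param clim pre-computed climatology (named list of 365-vectors for
#'   `vpd`, `ta`, `swi`, `vod`, `co2`, `paw_tall`, `paw_short`), or `NULL`
#'   for zero anomalies.
#'
#' @return a list: `E` (named evaporation components and `E_total`, mm/day,
#'   all fraction-weighted), `diag` (stress factors and PAW), `soils`
#'   (updated states), `drainage` (fraction-weighted, mm/day), `storage`
#'   (fraction-weighted end-of-day storage, mm).
#' @export
step_day <- function(forcing, soils, models, site, soil_par, params,
                     clim = NULL) {
  f <- as.list(forcing)
  doy <- fold_doy(as.Date(f$date))
  e_p <- priestley_taylor(f$Rn, f$Ta, params$alpha)

  e_i_area <- if (params$use_interception) {
    interception_simple(f$P, f$LAI, params$c_canopy)
  } else 0
  f_veg <- site$f_tall + site$f_short

  comp <- list(E_t_tall = 0, E_t_short = 0, E_b = 0,
               E_i = e_i_area * f_veg, E_w = params$e_w * site$f_water,
               E_s = params$e_s)
  diag <- list(S_t_tall = NA_real_, S_t_short = NA_real_, S_b = NA_real_,
               paw_tall = NA_real_, paw_short = NA_real_)
  drainage <- 0

  for (cls in c("tall", "short")) {
    frac <- site[[paste0("f_", cls)]]
    if (frac <= 0 || is.null(soils[[cls]])) next
    st <- soils[[cls]]
    paw <- st$paw
    cov <- tibble::tibble(
      paw = paw, vpd = f$VPD, ta = f$Ta, swi = f$SWi, vod = f$VOD,
      co2 = f$CO2,
      paw_anom = clim_anomaly(clim, paste0("paw_", cls), paw, doy),
      vpd_anom = clim_anomaly(clim, "vpd", f$VPD, doy),
      ta_anom = clim_anomaly(clim, "ta", f$Ta, doy),
      swi_anom = clim_anomaly(clim, "swi", f$SWi, doy),
      vod_anom = clim_anomaly(clim, "vod", f$VOD, doy),
      co2_anom = clim_anomaly(clim, "co2", f$CO2, doy))
    s_t <- clamp01(predict_stress(models[[cls]], cov,
                                  aux = list(vod = f$VOD, w_w = st$w_w)))
    upd <- step_water_balance(st, P = max(0, f$P - e_i_area),
                              E_t = s_t * e_p, E_b = 0,
                              params = soil_par[[cls]])
    soils[[cls]] <- upd$state
    comp[[paste0("E_t_", cls)]] <- upd$E_t * frac
    drainage <- drainage + upd$drainage * frac
    diag[[paste0("S_t_", cls)]] <- s_t
    diag[[paste0("paw_", cls)]] <- paw
  }

  if (site$f_bare > 0 && !is.null(soils$bare)) {
    s_b <- process_sb(soils$bare$w_1, soil_par$bare)
    upd <- step_water_balance(soils$bare, P = f$P, E_t = 0,
                              E_b = s_b * e_p, params = soil_par$bare)
    soils$bare <- upd$state
    comp$E_b <- upd$E_b * site$f_bare
    drainage <- drainage + upd$drainage * site$f_bare
    diag$S_b <- s_b
  }

  comp$E_total <- comp$E_t_tall + comp$E_t_short + comp$E_b + comp$E_i +
    comp$E_w + comp$E_s
  storage <- 0
  for (cls in names(soils)) {
    frac <- site[[paste0("f_", cls)]]
    if (!is.null(soils[[cls]]) && frac > 0) {
      storage <- storage + frac * soil_storage(soils[[cls]], soil_par[[cls]])
    }
  }
  list(E = comp, diag = diag, soils = soils, drainage = drainage,
       storage = storage, e_p = e_p)
}

#' Run the coupled evaporation model over a daily forcing series
#'
#' Sequentially applies [step_day()] in either `hybrid` mode (learned
#' stress predictors) or `process` mode (the process stress formula wrapped
#' behind the same predictor interface). Covariate anomalies use a
#' climatology pre-computed from the forcing archive; the plant-available
#' water climatology is taken from a preliminary process-mode pass so that
#' the daily step remains a pure function. Forcing must be gap-free daily
#' data; missing days raise an error rather than being interpolated.
#'
#' @param forcing daily forcing tibble (as from [generate_forcing()]).
#' @param site a [site_meta()].
#' @param mode `"hybrid"` or `"process"`.
#' @param models named list with entries `tall` and/or `short`: learned
#'   models for hybrid mode. Ignored in process mode. A process predictor
#'   from [process_stress_model()] may be supplied here in hybrid mode, in
#'   which case the run reproduces process mode exactly.
#' @param params a [run_params()]; `vod_max` defaults to the 99th
#'   percentile of the forcing VOD when not supplied.
#' @param soil_par named list of [soil_params()] for `tall`, `short`,
#'   `bare` (defaults constructed per class).
#' @param init_w initial volumetric moisture (default: critical moisture).
#' @param climatology `NULL` to build from the forcing archive (needs >= 1
#'   year; shorter series fall back to zero anomalies), or a pre-built
#'   climatology list, or `FALSE` for zero anomalies.
#'
#' @return a tibble with one row per day: evaporation components (mm/day,
#'   fraction-weighted), stress diagnostics, plant-available water, drainage
#'   and column storage.
#' @export
run_model <- function(forcing, site, mode = c("hybrid", "process"),
                      models = NULL, params = NULL, soil_par = NULL,
                      init_w = NULL, climatology = NULL) {
  mode <- match.arg(mode)
  if (NROW(forcing) == 0L) stop_arg("forcing is empty")
  dd <- diff(as.numeric(as.Date(forcing$date)))
  if (any(dd != 1)) {
    stop_arg("forcing has gaps or duplicate days at positions: ",
             paste(utils::head(which(dd != 1), 5), collapse = ", "))
  }
  if (is.null(soil_par)) {
    soil_par <- list(tall = soil_params("tall"), short = soil_params("short"),
                     bare = soil_params("bare"))
  }
  if (is.null(params)) {
    params <- run_params(vod_max = compute_vodmax(forcing$VOD))
  }
  if (mode == "process") {
    models <- list(tall = process_stress_model(soil_par$tall, params$vod_max),
                   short = process_stress_model(soil_par$short,
                                                params$vod_max))
  }
  if (is.null(models)) stop_arg("hybrid mode requires stress models")

  soils <- list()
  for (cls in c("tall", "short", "bare")) {
    frac <- site[[paste0("f_", cls)]]
    if (frac > 0) {
      soils[[cls]] <- soil_state_init(
        soil_par[[cls]],
        w = if (is.null(init_w)) soil_par[[cls]]$w_c else init_w)
    }
  }

  clim <- NULL
  if (is.null(climatology) && nrow(forcing) >= 365L) {
    clim <- build_run_climatology(forcing, site, soil_par, params,
                                  init_soils = soils)
  } else if (is.list(climatology)) {
    clim <- climatology
  }

  n <- nrow(forcing)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    out <- step_day(forcing[i, ], soils, models, site, soil_par, params,
                    clim = clim)
    soils <- out$soils
    rows[[i]] <- c(list(date = forcing$date[i]), out$E, out$diag,
                   list(drainage = out$drainage, storage = out$storage,
                        e_p = out$e_p))
  }
  out <- tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r)
  })))
  out$date <- forcing$date
  out
}

## climatology of the drivers from the forcing archive plus a PAW
## climatology from a preliminary process-mode pass
build_run_climatology <- function(forcing, site, soil_par, params,
                                  init_soils) {
  clim <- list(vpd = doy_climatology(forcing$VPD, forcing$date),
               ta = doy_climatology(forcing$Ta, forcing$date),
               swi = doy_climatology(forcing$SWi, forcing$date),
               vod = doy_climatology(forcing$VOD, forcing$date),
               co2 = doy_climatology(forcing$CO2, forcing$date))
  models <- list(tall = process_stress_model(soil_par$tall, params$vod_max),
                 short = process_stress_model(soil_par$short,
                                              params$vod_max))
  soils <- init_soils
  n <- nrow(forcing)
  paw_t <- paw_s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    out <- step_day(forcing[i, ], soils, models, site, soil_par, params,
                    clim = NULL)
    soils <- out$soils
    paw_t[i] <- out$diag$paw_tall
    paw_s[i] <- out$diag$paw_short
  }
  if (!all(is.na(paw_t))) {
    clim$paw_tall <- doy_climatology(paw_t, forcing$date)
  }
  if (!all(is.na(paw_s))) {
    clim$paw_short <- doy_climatology(paw_s, forcing$date)
  }
  clim
}

#' Run the coupled model over independent grid cells
#'
#' Cells are fully independent columns; the output is a long table with a
#' `cell` column (the list names), a text-based gridded format that keeps
#' runs inspectable and order-invariant.
#'
#' @param cells named list of daily forcing tibbles, one per grid cell.
#' @param site a [site_meta()] shared by all cells, or a named list of them.
#' @param ... passed to [run_model()].
#' @return a tibble of per-day outputs with a leading `cell` column.
#' @export
run_grid <- function(cells, site, ...) {
  if (is.null(names(cells)) || any(names(cells) == "")) {
    stop_arg("cells must be a named list of forcing tables")
  }
  per_cell <- lapply(names(cells), function(id) {
    s <- if (inherits(site, "site_meta")) site else site[[id]]
    out <- run_model(cells[[id]], s, ...)
    out$cell <- id
    out[, c("cell", setdiff(names(out), "cell"))]
  })
  do.call(rbind, per_cell)
}
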