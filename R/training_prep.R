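#' Covariate schema of the learned stress model
#'
#' Fixed feature ordering of the 12-dimensional covariate vector: the
#' absolute value of each driver followed by its seasonal anomaly, drivers
#' ordered PAW, VPD, Ta, SWi, VOD, CO2.
#'
#' @return character vector of the 12 feature names.
#' @export
covariate_schema <- function() {
  c("paw", "vpd", "ta", "swi", "vod", "co2",
    "paw_anom", "vpd_anom", "ta_anom", "swi_anom", "vod_anom", "co2_anom")
}

#' Partition transpiration from observed evaporation using leaf area
#'
#' Empirical ratio model `E_t = r(LAI) * E_obs` with a monotone saturating
#' ratio `r = 1 - exp(-k * LAI)`: dense canopies route most of the observed
#' evaporation through transpiration. The per-class rate constants are
#' configurable placeholders for fitted partitioning coefficients.
#'
#' @param E_obs observed evaporation, mm/day (>= 0, vectorised).
#' @param LAI leaf area index, m2/m2 (>= 0).
#' @param veg_class `"tall"` or `"short"`; selects the default `k`.
#' @param k rate constant overriding the class default
#'   (tall 0.45, short 0.75).
#' @return transpiration `E_t`, mm/day.
#' @export
#' @examples
#' partition_et(3, 2, k = 0.6) # 3 * (1 - exp(-1.2))
partition_et <- function(E_obs, LAI, veg_class = c("tall", "short"),
                         k = NULL) {
  if (any(!is.finite(E_obs)) || any(E_obs < 0)) {
    stop_arg("E_obs must be finite and >= 0")
  }
  if (any(!is.finite(LAI)) || any(LAI < 0)) {
    stop_arg("LAI must be finite and >= 0")
  }
  if (is.null(k)) {
    veg_class <- match.arg(veg_class)
    k <- if (veg_class == "tall") 0.45 else 0.75
  }
  (1 - exp(-k * LAI)) * E_obs
}

#' Remove rainy days from a site table
#'
#' Days with precipitation above the threshold are dropped to limit the
#' influence of interception loss and wet-sensor error on the observed
#' evaporation.
#'
#' @param series a data frame with a precipitation column `P` (mm/day).
#' @param rain_threshold rain-day threshold, mm/day (default 0.5).
#' @return a list: `retained` (the filtered data frame), `n_retained`,
#'   `n_removed`.
#' @export
filter_rain_days <- function(series, rain_threshold = 0.5) {
  if (!"P" %in% names(series)) stop_arg("series must have a column 'P'")
  keep <- !(series$P > rain_threshold)
  list(retained = series[keep, , drop = FALSE],
       n_retained = sum(keep),
       n_removed = sum(!keep))
}

#' Transpiration stress target from observed and potential transpiration
#'
#' `S_t = E_t / E_pt`, clamped to \[0, 1\]. Days with potential
#' transpiration at or below `ept_min` are dropped (the ratio is unstable
#' near zero) and counted rather than failed.
#'
#' @param E_t transpiration, mm/day.
#' @param E_pt_scaled potential transpiration, mm/day (bias-corrected where
#'   applicable).
#' @param ept_min minimum usable potential transpiration, mm/day
#'   (default 0.1).
#' @return a list: `s_t` (targets, `NA` on dropped days), `kept` (logical),
#'   `n_dropped`.
#' @export
#' @examples
#' stress_target(2, 4)$s_t # 0.5
stress_target <- function(E_t, E_pt_scaled, ept_min = 0.1) {
  if (length(E_t) != length(E_pt_scaled)) {
    stop_arg("E_t and E_pt_scaled must have equal length")
  }
  kept <- is.finite(E_pt_scaled) & E_pt_scaled > ept_min & is.finite(E_t)
  s <- rep(NA_real_, length(E_t))
  s[kept] <- clamp01(E_t[kept] / E_pt_scaled[kept])
  list(s_t = s, kept = kept, n_dropped = sum(!kept))
}

#' Projected crown area from basal area and site climate
#'
#' Allometric model
#' `ln A_c = -2.53 + 0.602 ln A_b + 0.0960 MAT - 5.48e-5 MAP`
#' relating a tree's projected crown area to its trunk basal area at breast
#' height and the site's mean annual temperature and precipitation
#' (natural-log form, areas in m2).
#'
#' @param A_b basal area, m2 (> 0, vectorised).
#' @param MAT site mean annual temperature, degC.
#' @param MAP site mean annual precipitation, mm/yr.
#' @param coef the four model coefficients (intercept, log-basal-area slope,
#'   MAT slope, MAP slope).
#' @return projected crown area `A_c`, m2.
#' @export
#' @examples
#' crown_area(1, 0, 0) # exp(-2.53)
crown_area <- function(A_b, MAT, MAP,
                       coef = c(-2.53, 0.602, 0.0960, -5.48e-5)) {
  if (any(!is.finite(A_b)) || any(A_b <= 0)) stop_arg("A_b must be > 0")
  exp(coef[1] + coef[2] * log(A_b) + coef[3] * MAT + coef[4] * MAP)
}

#' Upscale per-tree sap flow to stand transpiration
#'
#' Each tree's sap flow (cm3/h) is expressed per unit projected crown area
#' (from the allometric model), averaged over trees within species, and the
#' species means are combined as a basal-area-weighted average. Unit
#' conversion: 1 mm/day over 1 m2 of crown equals 1000 cm3/day, so
#' `mm/day = cm3/h / A_c * 24 / 1000`.
#'
#' @param flows long table with columns `date`, `tree_id`, `sap_cm3_h`.
#' @param trees tree metadata with columns `tree_id`, `species`, `A_b` (m2).
#' @param MAT,MAP site climate for the crown-area model.
#' @return a tibble with `date` and stand transpiration `e_t` (mm/day).
#' @export
upscale_sapflow <- function(flows, trees, MAT, MAP) {
  if (NROW(trees) < 1L) stop_arg("at least one tree is required")
  bad <- !is.finite(trees$A_b) | trees$A_b <= 0
  if (any(bad)) {
    warning(sum(bad), " tree(s) dropped: missing or non-positive basal area")
    trees <- trees[!bad, , drop = FALSE]
    if (NROW(trees) == 0L) stop_arg("no trees with valid basal area")
    flows <- flows[flows$tree_id %in% trees$tree_id, , drop = FALSE]
  }
  trees$A_c <- crown_area(trees$A_b, MAT, MAP)

  m <- merge(flows, trees[, c("tree_id", "species", "A_c")], by = "tree_id")
  m$v_mm_day <- m$sap_cm3_h / m$A_c * 24 / 1000

  ## tree -> species mean per day
  sp_day <- stats::aggregate(v_mm_day ~ date + species, data = m, FUN = mean)
  ## basal-area weight per species
  w <- stats::aggregate(A_b ~ species, data = trees, FUN = sum)
  w$wt <- w$A_b / sum(w$A_b)
  sp_day <- merge(sp_day, w[, c("species", "wt")], by = "species")
  sp_day$vw <- sp_day$v_mm_day * sp_day$wt
  out <- stats::aggregate(vw ~ date, data = sp_day, FUN = sum)
  tibble::tibble(date = out$date, e_t = out$vw)
}

#' Seasonal anomaly relative to a smoothed day-of-year climatology
#'
#' The climatology is the mean over years for each day of year, smoothed
#' with a centred circular moving window (default 31 days); the anomaly is
#' the raw departure of each value from the climatology on its day of year.
#' Requires at least one full year of data. Day 366 is folded onto day 365.
#'
#' @param x value series.
#' @param dates matching `Date` vector.
#' @param window smoothing window length in days (odd; default 31).
#' @return the anomaly series (same length as `x`).
#' @export
seasonal_anomaly <- function(x, dates, window = 31) {
  if (length(x) != length(dates)) stop_arg("x and dates must match")
  if (length(x) < 365L) {
    stop_arg("seasonal_anomaly needs at least one full year of data")
  }
  clim_s <- doy_climatology(x, dates, window)
  x - clim_s[fold_doy(dates)]
}

#' Build the supervised training table from site observation series
#'
#' Assembles, per site: seasonal anomalies of the six drivers, optional
#' LAI-based transpiration partitioning of the observed evaporation,
#' optional bias correction of the potential transpiration on the post-rain
#' subset, rain-day filtering, and the stress target
#' `S_t = E_t / E_pt` (clamped to \[0,1\], low-potential days dropped).
#'
#' @param sites a single observation tibble (from
#'   [generate_observations()], or a real site table with the same columns)
#'   or a list of them. Required columns: `date`, `P`, `Ta`, `VPD`, `SWi`,
#'   `VOD`, `CO2`, `LAI`, `paw`, `e_pt_raw`, `e_obs`.
#' @param partition apply [partition_et()] to `e_obs` (use when `e_obs` is
#'   total evaporation; leave `FALSE` when it is already transpiration,
#'   e.g. sap-flow-derived series).
#' @param veg_class vegetation class for the partition ratio.
#' @param scale_ept bias-correct `e_pt_raw` against the observed
#'   transpiration on post-rain days via [scale_ept()] (use when the
#'   potential series comes from a mismatched spatial scale).
#' @param rain_threshold rain-day threshold, mm/day.
#' @param ept_min minimum usable potential transpiration, mm/day.
#' @param anomaly_window climatology smoothing window, days.
#'
#' @return a tibble with `site_id`, `date`, the 12 [covariate_schema()]
#'   features, the target `s_t`, and `s_t_true` where the input carried the
#'   generator truth. Attributes `n_rain_removed` and `n_ept_dropped` count
#'   discarded days.
#' @export
build_training_table <- function(sites, partition = FALSE,
                                 veg_class = "short", scale_ept = FALSE,
                                 rain_threshold = 0.5, ept_min = 0.1,
                                 anomaly_window = 31) {
  if (is.data.frame(sites)) sites <- list(sites)
  pieces <- vector("list", length(sites))
  n_rain <- 0L
  n_ept <- 0L
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    need <- c("date", "P", "Ta", "VPD", "SWi", "VOD", "CO2", "LAI",
              "paw", "e_pt_raw", "e_obs")
    if (!all(need %in% names(s))) {
      stop_arg("site table lacks columns: ",
               paste(setdiff(need, names(s)), collapse = ", "))
    }
    e_t <- if (partition) {
      partition_et(s$e_obs, s$LAI, veg_class)
    } else {
      s$e_obs
    }
    ept <- if (scale_ept) {
      flags <- rain_flags(s$P, rain_threshold)
      scale_ept(s$e_pt_raw, e_t, subset = flags$post_rain)
    } else {
      s$e_pt_raw
    }

    feat <- tibble::tibble(
      site_id = if ("site_id" %in% names(s)) s$site_id else
        sprintf("S%03d", i),
      date = s$date,
      P = s$P,
      paw = s$paw, vpd = s$VPD, ta = s$Ta, swi = s$SWi,
      vod = s$VOD, co2 = s$CO2,
      paw_anom = seasonal_anomaly(s$paw, s$date, anomaly_window),
      vpd_anom = seasonal_anomaly(s$VPD, s$date, anomaly_window),
      ta_anom = seasonal_anomaly(s$Ta, s$date, anomaly_window),
      swi_anom = seasonal_anomaly(s$SWi, s$date, anomaly_window),
      vod_anom = seasonal_anomaly(s$VOD, s$date, anomaly_window),
      co2_anom = seasonal_anomaly(s$CO2, s$date, anomaly_window),
      e_t = e_t, e_pt = ept)
    if ("s_t_true" %in% names(s)) feat$s_t_true <- s$s_t_true

    fr <- filter_rain_days(feat, rain_threshold)
    n_rain <- n_rain + fr$n_removed
    feat <- fr$retained
    tg <- stress_target(feat$e_t, feat$e_pt, ept_min)
    n_ept <- n_ept + tg$n_dropped
    feat$s_t <- tg$s_t
    pieces[[i]] <- feat[tg$kept, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  out <- out[, c("site_id", "date", covariate_schema(), "s_t",
                 intersect("s_t_true", names(out)))]
  attr(out, "n_rain_removed") <- n_rain
  attr(out, "n_ept_dropped") <- n_ept
  out
}
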