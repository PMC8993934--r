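#' Climate parameter set for the synthetic forcing generator
#'
#' Parameters of the seeded weather generator used to emulate daily site
#' forcing. Rain occurrence follows a two-state first-order chain with
#' dry-to-wet probability `rain_p01` and wet-to-wet probability `rain_p11`
#' (stationary wet-day probability `p01 / (1 + p01 - p11)`); wet-day depths
#' are exponential with mean `rain_mean` mm. Temperature, shortwave
#' radiation, vegetation optical depth and leaf area follow seasonal
#' harmonics with AR(1) residuals; vapour pressure deficit is derived from
#' temperature and a humidity state that is higher on wet days; CO2 carries
#' a linear trend plus a seasonal drawdown cycle.
#'
#' @param MAT mean annual air temperature, degC.
#' @param ta_amp seasonal temperature amplitude, degC.
#' @param ta_sd,ta_ar sd and lag-1 coefficient of the AR(1) temperature
#'   residual.
#' @param swi_base,swi_amp mean and seasonal amplitude of incoming shortwave
#'   radiation, W/m2.
#' @param rain_p01,rain_p11 rain occurrence chain probabilities.
#' @param rain_mean mean wet-day precipitation depth, mm.
#' @param vod_base,vod_amp mean and seasonal amplitude of vegetation optical
#'   depth.
#' @param lai_base,lai_amp mean and seasonal amplitude of leaf area index,
#'   m2/m2.
#' @param co2_0 CO2 concentration at the series start, ppm.
#' @param co2_trend CO2 trend, ppm/year.
#' @param season_peak day of year of the seasonal maximum (default 196,
#'   mid July; use ~15 for a southern-hemisphere site).
#'
#' @return a list of class `climate_params`.
#' @export
default_climate <- function(MAT = 12, ta_amp = 10, ta_sd = 1.5, ta_ar = 0.7,
                            swi_base = 180, swi_amp = 140,
                            rain_p01 = 0.2, rain_p11 = 0.55, rain_mean = 6,
                            vod_base = 0.8, vod_amp = 0.3,
                            lai_base = 2.5, lai_amp = 1.8,
                            co2_0 = 400, co2_trend = 2.3,
                            season_peak = 196) {
  structure(as.list(environment()), class = "climate_params")
}

#' Generate a seeded daily forcing series
#'
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param n_days number of days (>= 1).
#' @param climate a [default_climate()] parameter set.
#' @param start_date first calendar day (default "2000-01-01").
#'
#' @return a tibble with one row per day: `date`, `P` (mm/day), `Rn` (W/m2),
#'   `Ta` (degC), `VPD` (kPa), `SWi` (W/m2), `VOD` (-), `CO2` (ppm),
#'   `LAI` (m2/m2).
#' @export
#' @examples
#' f <- generate_forcing(1, 365)
#' range(f$P)
generate_forcing <- function(seed, n_days, climate = default_climate(),
                             start_date = as.Date("2000-01-01")) {
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1) {
    stop_arg("n_days must be a positive integer")
  }
  n_days <- as.integer(n_days)
  set.seed(as.integer(seed))
  cl <- climate

  dates <- start_date + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  phase <- sin(2 * pi * (doy - (cl$season_peak - 91.3125)) / 365.25)

  ## rain occurrence chain + exponential depths
  wet <- logical(n_days)
  u <- runif(n_days)
  state <- FALSE
  for (i in seq_len(n_days)) {
    p <- if (state) cl$rain_p11 else cl$rain_p01
    state <- u[i] < p
    wet[i] <- state
  }
  P <- ifelse(wet, rexp(n_days, rate = 1 / cl$rain_mean), 0)

  ## AR(1) temperature residual
  eps <- rnorm(n_days, sd = cl$ta_sd)
  res <- numeric(n_days)
  res[1] <- eps[1]
  for (i in 2:max(2, n_days)) {
    if (i <= n_days) res[i] <- cl$ta_ar * res[i - 1] + eps[i]
  }
  Ta <- cl$MAT + cl$ta_amp * phase + res

  ## shortwave: seasonal cycle, cloudier (dimmer) on wet days
  SWi <- cl$swi_base + cl$swi_amp * phase + rnorm(n_days, sd = 15)
  SWi <- pmax(10, SWi) * ifelse(wet, 0.6, 1)
  Rn <- 0.62 * SWi + rnorm(n_days, sd = 8)

  ## VPD from saturation vapour pressure and a wet-day humidity state
  es <- 0.6108 * exp(17.27 * Ta / (Ta + 237.3))
  rh <- clamp(0.55 + 0.25 * wet + rnorm(n_days, sd = 0.08), 0.2, 0.98)
  VPD <- pmax(0, es * (1 - rh))

  ## phenology trails the radiation season by ~ one month
  phase_lag <- sin(2 * pi * (doy - (cl$season_peak + 30 - 91.3125)) / 365.25)
  VOD <- pmax(0.02, cl$vod_base + cl$vod_amp * phase_lag +
                as.numeric(stats::filter(rnorm(n_days, sd = 0.02), 0.8,
                                         method = "recursive")))
  LAI <- pmax(0.05, cl$lai_base + cl$lai_amp * phase_lag +
                rnorm(n_days, sd = 0.1))

  CO2 <- cl$co2_0 + cl$co2_trend * (seq_len(n_days) - 1) / 365.25 -
    3 * phase_lag

  tibble::tibble(date = dates, P = P, Rn = Rn, Ta = Ta, VPD = VPD,
                 SWi = SWi, VOD = VOD, CO2 = CO2, LAI = LAI)
}

#' Ground-truth transpiration stress specification
#'
#' Defines the known nonlinear stress function embedded in a synthetic world.
#' The `"default"` form is a smooth bounded product of physiologically shaped
#' responses: logistic in plant-available water, exponential decay in vapour
#' pressure deficit, a Gaussian temperature optimum, a saturating light
#' response, a `sqrt(VOD/VOD_max)` phenology factor and a weak linear CO2
#' modifier. The `"paw_only"` form, `min(1, PAW / paw_sat)`, saturates to 1
#' for moist soil and is used to build worlds that transpire at their
#' potential on days following rain. The `"constant"` form returns a fixed
#' value.
#'
#' @param form one of `"default"`, `"paw_only"`, `"constant"`.
#' @param noise_sd sd of the additive Gaussian observation noise on E,
#'   mm/day (truncated at zero).
#' @param params named list overriding individual shape parameters.
#'
#' @return an object of class `truth_stress_spec`.
#' @export
truth_stress_spec <- function(form = c("default", "paw_only", "constant"),
                              noise_sd = 0.05, params = list()) {
  form <- match.arg(form)
  defaults <- list(paw_k = 8, paw_mid = 0.3,
                   vpd_k = 0.25,
                   ta_opt = 20, ta_width = 18,
                   swi_k = 1 / 120,
                   vod_max = 1.2,
                   co2_ref = 400, co2_slope = 5e-5,
                   paw_sat = 0.5, value = 1)
  defaults[names(params)] <- params
  structure(list(form = form, noise_sd = noise_sd, params = defaults),
            class = "truth_stress_spec")
}

#' Evaluate a ground-truth stress function
#'
#' @param spec a [truth_stress_spec()].
#' @param paw,vpd,ta,swi,vod,co2 covariate vectors (recycled to a common
#'   length).
#' @return the true stress factor in \[0, 1\].
#' @export
truth_stress <- function(spec, paw, vpd, ta, swi, vod, co2) {
  p <- spec$params
  switch(spec$form,
    constant = rep_len(clamp01(p$value), length(paw)),
    paw_only = clamp01(paw / p$paw_sat),
    default = {
      f_paw <- 1 / (1 + exp(-p$paw_k * (paw - p$paw_mid)))
      f_vpd <- exp(-p$vpd_k * pmax(0, vpd))
      f_ta  <- exp(-((ta - p$ta_opt) / p$ta_width)^2)
      f_swi <- 1 - exp(-p$swi_k * pmax(0, swi))
      f_vod <- sqrt(pmin(pmax(vod, 0), p$vod_max) / p$vod_max)
      f_co2 <- clamp(1 - p$co2_slope * (co2 - p$co2_ref), 0.8, 1.2)
      clamp01(f_paw * f_vpd * f_ta * f_swi * f_vod * f_co2)
    })
}

#' Site metadata for a synthetic site
#'
#' @param site_id character site identifier.
#' @param veg_class dominant class, `"short"` or `"tall"`.
#' @param f_tall,f_short,f_bare,f_water sub-grid land-cover fractions in
#'   \[0, 1\], summing to at most 1.
#' @param MAT mean annual temperature, degC.
#' @param MAP mean annual precipitation, mm/yr.
#' @return an object of class `site_meta`.
#' @export
site_meta <- function(site_id, veg_class = c("short", "tall"),
                      f_tall = NULL, f_short = NULL, f_bare = 0.1,
                      f_water = 0, MAT = 12, MAP = 800) {
  veg_class <- match.arg(veg_class)
  if (is.null(f_tall)) f_tall <- if (veg_class == "tall") 0.8 else 0.1
  if (is.null(f_short)) f_short <- if (veg_class == "short") 0.8 else 0.1
  fr <- c(f_tall, f_short, f_bare, f_water)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12) {
    stop_arg("cover fractions must lie in [0,1] and sum to at most 1")
  }
  structure(list(site_id = site_id, veg_class = veg_class,
                 f_tall = f_tall, f_short = f_short, f_bare = f_bare,
                 f_water = f_water, MAT = MAT, MAP = MAP),
            class = "site_meta")
}

#' Generate noisy pseudo-observations of evaporation over a soil column
#'
#' Runs a soil water balance forward under the forcing, evaluates the
#' ground-truth stress on each day's start-of-day covariates, and emits an
#' observed-evaporation series `E_obs = S_true * E_pt + noise` on dry days;
#' rain days additionally carry a canopy-interception term so that
#' rain-day filtering has real work to do. The true stress series and the
#' soil diagnostics are retained so that recovery experiments can compare
#' against the embedded truth.
#'
#' @param forcing tibble from [generate_forcing()] (non-empty).
#' @param truth a [truth_stress_spec()].
#' @param params a [soil_params()] object for the site's soil column.
#' @param seed integer RNG seed for the observation noise.
#' @param rain_threshold rain-day threshold, mm/day.
#' @param c_canopy interception capacity per unit LAI, mm/day.
#' @param soil_evap_frac fraction of potential evaporation additionally
#'   extracted from the surface layer as soil evaporation. Default 0: the
#'   column then follows exactly the same physics as the coupled model's
#'   vegetated column, so covariates seen in training match those produced
#'   during coupled runs. It never enters `E_obs`.
#'
#' @return a tibble: the forcing columns plus `paw`, `w_w`, `w_1`,
#'   `e_pt_raw` (potential transpiration, mm/day), `s_t_true`, `e_t_true`
#'   (mm/day), `e_obs` (mm/day), `rain_day`, `post_rain`.
#' @export
generate_observations <- function(forcing, truth, params, seed,
                                  rain_threshold = 0.5, c_canopy = 0.5,
                                  soil_evap_frac = 0) {
  if (NROW(forcing) == 0L) stop_arg("forcing must be non-empty")
  set.seed(as.integer(seed))
  n <- nrow(forcing)
  state <- soil_state_init(params)

  e_pt <- priestley_taylor(forcing$Rn, forcing$Ta)
  paw <- w_w <- w_1 <- s_true <- e_t <- numeric(n)
  for (i in seq_len(n)) {
    paw[i] <- state$paw
    w_w[i] <- state$w_w
    w_1[i] <- state$w_1
    s_true[i] <- truth_stress(truth, paw[i], forcing$VPD[i], forcing$Ta[i],
                              forcing$SWi[i], forcing$VOD[i], forcing$CO2[i])
    e_t[i] <- s_true[i] * e_pt[i]
    e_i <- interception_simple(forcing$P[i], forcing$LAI[i], c_canopy)
    e_b <- soil_evap_frac * process_sb(state$w_1, params) * e_pt[i]
    ## soil extraction may be capped in very dry soil; the observation model
    ## stays E_obs = S_true * E_pt (the cap only shapes the PAW trajectory)
    st <- step_water_balance(state, P = max(0, forcing$P[i] - e_i),
                             E_t = e_t[i], E_b = e_b, params = params)
    state <- st$state
  }

  flags <- rain_flags(forcing$P, rain_threshold)
  noise <- if (truth$noise_sd > 0) rnorm(n, sd = truth$noise_sd) else 0
  e_i_all <- interception_simple(forcing$P, forcing$LAI, c_canopy)
  e_obs <- pmax(0, e_t + noise + ifelse(flags$rain_day, e_i_all, 0))

  out <- forcing
  out$paw <- paw
  out$w_w <- w_w
  out$w_1 <- w_1
  out$e_pt_raw <- e_pt
  out$s_t_true <- s_true
  out$e_t_true <- e_t
  out$e_obs <- e_obs
  out$rain_day <- flags$rain_day
  out$post_rain <- flags$post_rain
  out
}

#' Generate a per-tree daily sap-flow table
#'
#' Builds a stand of `n_trees` trees (lognormal basal areas, species labels),
#' derives each tree's projected crown area from the allometric model in
#' [crown_area()], and assigns per-tree sap-flow rates (cm3/h) consistent
#' with a stand transpiration equal to the embedded truth stress times the
#' potential transpiration, so that crown-area upscaling recovers the stand
#' series exactly when `tree_scatter = 0`.
#'
#' @param n_trees number of trees (>= 1).
#' @param n_days series length in days.
#' @param site a [site_meta()] (supplies MAT/MAP for the allometry and the
#'   site climate).
#' @param truth a [truth_stress_spec()].
#' @param seed integer RNG seed.
#' @param n_species number of species labels to draw.
#' @param tree_scatter sd of a per-tree lognormal scatter around the stand
#'   rate (0 = identical trees per unit crown area).
#'
#' @return a list: `trees` (tree_id, species, A_b m2, A_c m2), `flows`
#'   (date, tree_id, sap_cm3_h), and `stand` (the generating observation
#'   table, including the stand transpiration `e_t_true` in mm/day).
#' @export
generate_sapflow_table <- function(n_trees, n_days, site, truth, seed,
                                   n_species = 2, tree_scatter = 0) {
  if (!is.numeric(n_trees) || n_trees < 1) {
    stop_arg("n_trees must be a positive integer")
  }
  climate <- default_climate(MAT = site$MAT)
  forcing <- generate_forcing(derive_seed(seed, "sap-forcing"), n_days,
                              climate)
  obs <- generate_observations(forcing, truth,
                               soil_params("tall"),
                               seed = derive_seed(seed, "sap-obs"))

  set.seed(derive_seed(seed, "sap-trees"))
  trees <- tibble::tibble(
    tree_id = sprintf("T%03d", seq_len(n_trees)),
    species = paste0("sp", 1 + (seq_len(n_trees) - 1) %% n_species),
    A_b = exp(rnorm(n_trees, mean = log(0.07), sd = 0.5)))
  trees$A_c <- crown_area(trees$A_b, site$MAT, site$MAP)
  scatter <- if (tree_scatter > 0) {
    exp(rnorm(n_trees, sd = tree_scatter) - tree_scatter^2 / 2)
  } else rep(1, n_trees)

  ## sap flow per tree: stand rate (mm/day per m2 crown) x crown area,
  ## converted to cm3/h (1 mm over 1 m2 = 1000 cm3, spread over 24 h)
  flows <- do.call(rbind, lapply(seq_len(n_trees), function(k) {
    tibble::tibble(date = obs$date,
                   tree_id = trees$tree_id[k],
                   sap_cm3_h = obs$e_t_true * scatter[k] *
                     trees$A_c[k] * 1000 / 24)
  }))
  list(trees = trees, flows = flows, stand = obs)
}

#' Generate a multi-site synthetic training world
#'
#' Draws per-site climates (spread in mean temperature, rainfall regime,
#' phenology and radiation), runs the observation generator at each site
#' under a shared ground-truth stress function, and returns the per-site
#' tables. This is the default experimental setting for stress-function
#' recovery tests.
#'
#' @param seed integer master seed.
#' @param n_sites number of sites.
#' @param n_years series length per site, years.
#' @param truth a [truth_stress_spec()] shared by all sites.
#' @param veg_class soil/vegetation configuration for the site columns.
#'
#' @return a list with `sites` (list of observation tibbles, one per site)
#'   and `meta` (list of [site_meta()] objects).
#' @export
generate_world <- function(seed, n_sites = 40, n_years = 6,
                           truth = truth_stress_spec(),
                           veg_class = "short") {
  set.seed(as.integer(seed))
  draws <- tibble::tibble(
    MAT = runif(n_sites, 2, 24),
    ta_amp = runif(n_sites, 6, 14),
    swi_base = runif(n_sites, 140, 220),
    rain_p01 = runif(n_sites, 0.15, 0.30),
    rain_p11 = runif(n_sites, 0.40, 0.65),
    rain_mean = runif(n_sites, 3, 12),
    vod_base = runif(n_sites, 0.5, 1.0),
    lai_base = runif(n_sites, 1, 4))
  n_days <- as.integer(round(n_years * 365.25))
  sites <- vector("list", n_sites)
  meta <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    cl <- default_climate(MAT = draws$MAT[s], ta_amp = draws$ta_amp[s],
                          swi_base = draws$swi_base[s],
                          rain_p01 = draws$rain_p01[s],
                          rain_p11 = draws$rain_p11[s],
                          rain_mean = draws$rain_mean[s],
                          vod_base = draws$vod_base[s],
                          lai_base = draws$lai_base[s])
    forcing <- generate_forcing(derive_seed(seed, paste0("forcing", s)),
                                n_days, cl)
    sites[[s]] <- generate_observations(
      forcing, truth, soil_params(veg_class),
      seed = derive_seed(seed, paste0("obs", s)))
    sites[[s]]$site_id <- sprintf("S%03d", s)
    meta[[s]] <- site_meta(sprintf("S%03d", s), veg_class = veg_class,
                           MAT = draws$MAT[s],
                           MAP = draws$rain_mean[s] * 365.25 *
                             draws$rain_p01[s] /
                             (1 + draws$rain_p01[s] - draws$rain_p11[s]))
  }
  list(sites = sites, meta = meta)
}
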