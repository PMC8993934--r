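short_site <- function() {
  site_meta("X", "short", f_tall = 0, f_short = 0.8, f_bare = 0.2,
            f_water = 0)
}

test_that("hybrid mode with the process formula as predictor matches process mode exactly", {
  f <- generate_forcing(31, 400)
  site <- short_site()
  soil_par <- list(tall = soil_params("tall"), short = soil_params("short"),
                   bare = soil_params("bare"))
  params <- run_params(vod_max = compute_vodmax(f$VOD))
  process <- run_model(f, site, mode = "process", params = params,
                       soil_par = soil_par)
  models <- list(tall = process_stress_model(soil_par$tall, params$vod_max),
                 short = process_stress_model(soil_par$short,
                                              params$vod_max))
  hybrid <- run_model(f, site, mode = "hybrid", models = models,
                      params = params, soil_par = soil_par)
  expect_equal(hybrid, process, tolerance = 0)
})

test_that("zero stress shuts transpiration off; soil dries only via drainage and bare soil", {
  f <- generate_forcing(5, 200)
  site <- short_site()
  models <- list(tall = constant_stress_model(0),
                 short = constant_stress_model(0))
  out <- run_model(f, site, mode = "hybrid", models = models,
                   climatology = FALSE)
  expect_true(all(out$E_t_short == 0))
  expect_true(all(out$E_t_tall == 0))
  expect_true(any(out$E_b > 0))
})

test_that("a year-long coupled run conserves water to under 1e-6 mm", {
  f <- generate_forcing(91, 365)
  site <- short_site()
  out <- run_model(f, site, mode = "process")
  storage0 <- 0.8 * 0.30 * (100 + 900) + 0.2 * 0.30 * 100
  closure <- sum(f$P) - sum(out$E_total) - sum(out$drainage) -
    (out$storage[365] - storage0)
  expect_lt(abs(closure), 1e-6)
})

test_that("day-two plant-available water reflects day-one extraction", {
  f <- generate_forcing(3, 2, default_climate(rain_p01 = 0, rain_p11 = 0))
  site <- site_meta("Y", "short", f_tall = 0, f_short = 1, f_bare = 0,
                    f_water = 0)
  sp <- soil_params("short")
  models <- list(short = constant_stress_model(0.5))
  out <- run_model(f, site, mode = "hybrid", models = models,
                   soil_par = list(short = sp),
                   init_w = c(0.29, 0.20), climatology = FALSE)
  # hand oracle: day 1 PAW from w_w = 0.29; extraction 0.5 * E_p from the
  # wettest (surface, 100 mm) layer sets day-2 w_w and PAW
  e_p1 <- priestley_taylor(f$Rn[1], f$Ta[1])
  expect_equal(out$paw_short[1], (0.29 - 0.15) / 0.15)
  w1_day2 <- 0.29 - 0.5 * e_p1 / 100
  expect_equal(out$paw_short[2], (max(w1_day2, 0.20) - 0.15) / 0.15)
  expect_equal(out$E_t_short[1], 0.5 * e_p1)
})

test_that("evaporation never exceeds the fraction-weighted potential", {
  f <- generate_forcing(17, 365)
  out <- run_model(f, short_site(), mode = "process")
  expect_true(all(out$E_t_tall + out$E_t_short + out$E_b <=
                    out$e_p * (0.8 + 0.2) + 1e-12))
})

test_that("switching interception off changes output first on the first wet day", {
  f <- generate_forcing(13, 120)
  site <- short_site()
  p_on <- run_params(vod_max = compute_vodmax(f$VOD))
  p_off <- run_params(vod_max = compute_vodmax(f$VOD),
                      use_interception = FALSE)
  on <- run_model(f, site, mode = "process", params = p_on,
                  climatology = FALSE)
  off <- run_model(f, site, mode = "process", params = p_off,
                   climatology = FALSE)
  i0 <- which(f$P > 0)[1]
  if (i0 > 1) {
    expect_equal(on$E_total[1:(i0 - 1)], off$E_total[1:(i0 - 1)])
  }
  e_i_expected <- min(f$P[i0], 0.5 * f$LAI[i0]) * 0.8
  expect_equal(on$E_total[i0] - off$E_total[i0], e_i_expected)
  expect_gt(on$E_i[i0], 0)
})

test_that("grid cells are independent and order-invariant", {
  cells <- list(a = generate_forcing(1, 120), b = generate_forcing(2, 120))
  site <- short_site()
  g1 <- run_grid(cells, site, mode = "process", climatology = FALSE)
  g2 <- run_grid(rev(cells), site, mode = "process", climatology = FALSE)
  for (id in c("a", "b")) {
    expect_equal(g1[g1$cell == id, ], g2[g2$cell == id, ],
                 ignore_attr = TRUE)
  }
  solo <- run_model(cells$b, site, mode = "process", climatology = FALSE)
  expect_equal(g1[g1$cell == "b", names(solo)], solo, ignore_attr = TRUE)
})

test_that("missing forcing days raise a gap error, not silent interpolation", {
  f <- generate_forcing(1, 60)
  expect_error(run_model(f[-10, ], short_site(), mode = "process",
                         climatology = FALSE), "gap")
})

test_that("the hybrid run with the trained model tracks the truth world's evaporation", {
  f <- generate_forcing(404, 731)
  obs <- generate_observations(f, truth_stress_spec(), soil_params("short"),
                               seed = 405)
  site <- site_meta("Z", "short", f_tall = 0, f_short = 1, f_bare = 0,
                    f_water = 0)
  m <- default_stress_model()
  out <- run_model(f, site, mode = "hybrid",
                   models = list(short = m),
                   soil_par = list(short = soil_params("short")))
  expect_gte(kge(out$E_t_short, obs$e_t_true)$kge, 0.85)
})
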