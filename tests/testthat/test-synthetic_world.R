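test_that("forcing generator honours its contract and determinism", {
  f <- generate_forcing(1, 365)
  expect_equal(nrow(f), 365)
  expect_true(all(f$P >= 0) && all(f$SWi >= 0) && all(f$VPD >= 0) &&
                all(f$VOD >= 0) && all(f$LAI >= 0))
  expect_identical(f, generate_forcing(1, 365))
  expect_error(generate_forcing(1, 0), "positive")
})

test_that("zero wet-day probability yields a rain-free series", {
  cl <- default_climate(rain_p01 = 0, rain_p11 = 0)
  f <- generate_forcing(3, 200, cl)
  expect_true(all(f$P == 0))
})

test_that("forcing invariants hold across many seeds", {
  ok <- TRUE
  for (s in 1:100) {
    f <- generate_forcing(s, 90)
    ok <- ok && all(f$P >= 0) && all(f$SWi >= 0) && all(f$VPD >= 0) &&
      all(f$VOD >= 0) && all(f$LAI >= 0) && all(is.finite(f$Ta)) &&
      all(f$CO2 > 0)
  }
  expect_true(ok)
})

test_that("site fractions are validated", {
  s <- site_meta("A", "tall", MAT = 8, MAP = 600)
  expect_equal(s$f_tall + s$f_short + s$f_bare + s$f_water, 1)
  expect_error(site_meta("B", "short", f_tall = 0.8, f_short = 0.5),
               "fractions")
})

test_that("noise-free observations reproduce the truth stress exactly on dry days", {
  f <- generate_forcing(10, 730)
  obs <- generate_observations(f, truth_stress_spec(noise_sd = 0),
                               soil_params("short"), seed = 3, c_canopy = 0)
  dry <- !obs$rain_day
  expect_equal(obs$e_obs[dry], (obs$s_t_true * obs$e_pt_raw)[dry])
  expect_equal(obs$e_obs[dry] / obs$e_pt_raw[dry], obs$s_t_true[dry])
})

test_that("an unstressed truth world transpires at its potential on dry days", {
  f <- generate_forcing(10, 365)
  obs <- generate_observations(
    f, truth_stress_spec("constant", noise_sd = 0, params = list(value = 1)),
    soil_params("short"), seed = 5, c_canopy = 0)
  ept_independent <- priestley_taylor(f$Rn, f$Ta)  # recomputed outside
  dry <- !obs$rain_day
  expect_equal(obs$e_obs[dry], ept_independent[dry], tolerance = 1e-12)
})

test_that("observation generation is reproducible and rain days carry interception", {
  f <- generate_forcing(4, 400)
  a <- generate_observations(f, truth_stress_spec(), soil_params("short"), 9)
  b <- generate_observations(f, truth_stress_spec(), soil_params("short"), 9)
  expect_identical(a, b)
  wet <- a$rain_day & a$P > 1
  expect_true(all(a$e_obs[wet] >=
                    (a$s_t_true * a$e_pt_raw)[wet] - 3 * 0.05))
  expect_error(generate_observations(f[0, ], truth_stress_spec(),
                                     soil_params("short"), 1), "non-empty")
})

test_that("truth stress spans (0,1) and responds to every covariate", {
  spec <- truth_stress_spec()
  base <- truth_stress(spec, 0.5, 1, 20, 200, 0.8, 400)
  expect_gt(base, 0); expect_lt(base, 1)
  expect_gt(truth_stress(spec, 0.9, 1, 20, 200, 0.8, 400), base)  # wetter
  expect_lt(truth_stress(spec, 0.5, 3, 20, 200, 0.8, 400), base)  # drier air
  expect_lt(truth_stress(spec, 0.5, 1, 45, 200, 0.8, 400), base)  # too hot
  expect_lt(truth_stress(spec, 0.5, 1, 20, 30, 0.8, 400), base)   # dim light
  expect_lt(truth_stress(spec, 0.5, 1, 20, 200, 0.2, 400), base)  # low VOD
})

test_that("sap-flow upscaling round-trips the generating stand transpiration", {
  site <- site_meta("SF", "tall", MAT = 10, MAP = 800)
  one <- generate_sapflow_table(1, 400, site, truth_stress_spec(noise_sd = 0),
                                seed = 6)
  up <- upscale_sapflow(one$flows, one$trees, MAT = 10, MAP = 800)
  expect_equal(up$e_t[order(up$date)], one$stand$e_t_true, tolerance = 1e-12)

  # identical trees: species weighting is a no-op
  many <- generate_sapflow_table(6, 120, site, truth_stress_spec(noise_sd = 0),
                                 seed = 6, n_species = 3)
  upm <- upscale_sapflow(many$flows, many$trees, MAT = 10, MAP = 800)
  expect_equal(upm$e_t[order(upm$date)], many$stand$e_t_true,
               tolerance = 1e-12)

  # seeded reproducibility
  again <- generate_sapflow_table(6, 120, site,
                                  truth_stress_spec(noise_sd = 0),
                                  seed = 6, n_species = 3)
  expect_identical(many$flows, again$flows)
})
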