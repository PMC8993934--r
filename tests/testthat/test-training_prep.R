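test_that("LAI partition ratio is zero at zero leaf area and saturates to 1", {
  expect_equal(partition_et(3, 0), 0)
  expect_equal(partition_et(3, 50), 3, tolerance = 1e-9)
  expect_equal(partition_et(3, 2, k = 0.6), 3 * (1 - exp(-1.2)))
  lai <- seq(0, 8, 0.1)
  expect_true(all(diff(partition_et(1, lai, k = 0.45)) >= 0))
  expect_error(partition_et(3, -1), "LAI")
})

test_that("rain-day filtering counts retained and removed days", {
  df <- data.frame(P = c(0, 0, 2, 0, 5, 0.4, 1, 0, 0, 0))
  out <- filter_rain_days(df, rain_threshold = 0.5)
  expect_equal(out$n_retained, 7)
  expect_equal(out$n_removed, 3)
  dry <- data.frame(P = rep(0, 5))
  expect_equal(filter_rain_days(dry)$n_removed, 0)
  expect_equal(filter_rain_days(df, rain_threshold = Inf)$n_removed, 0)
})

test_that("stress targets are the clamped flux-to-potential ratio", {
  expect_equal(stress_target(2, 4)$s_t, 0.5)
  expect_equal(stress_target(3, 3)$s_t, 1)
  expect_equal(stress_target(0, 3)$s_t, 0)
  expect_equal(stress_target(5, 3)$s_t, 1)  # clamped above potential
  out <- stress_target(c(1, 1, 1), c(2, 0.05, 0.2), ept_min = 0.1)
  expect_equal(out$n_dropped, 1)
  expect_true(is.na(out$s_t[2]))
})

test_that("crown-area allometry matches hand arithmetic", {
  # coefficients of the fitted model, echoed from the default argument
  expect_equal(eval(formals(crown_area)$coef),
               c(-2.53, 0.602, 0.0960, -5.48e-5))
  expect_equal(crown_area(1, 0, 0), exp(-2.53))
  expect_equal(crown_area(0.05, 10, 800),
               exp(-2.53 + 0.602 * log(0.05) + 0.96 - 5.48e-5 * 800))
  expect_equal(crown_area(0.05, 10, 800), 0.0328, tolerance = 1e-2)
  expect_error(crown_area(0, 10, 800), "A_b")
})

test_that("sap-flow upscaling weights species by basal area", {
  # two species, basal-area weights 0.75/0.25, per-crown rates 2 and 4 mm/day
  trees <- data.frame(tree_id = c("a", "b"), species = c("s1", "s2"),
                      A_b = c(3, 1))
  ac <- crown_area(trees$A_b, 10, 800)
  flows <- data.frame(date = as.Date("2000-01-01"),
                      tree_id = c("a", "b"),
                      sap_cm3_h = c(2, 4) * ac * 1000 / 24)
  expect_equal(upscale_sapflow(flows, trees, 10, 800)$e_t, 2.5)

  # invariant to row order and species relabelling
  flows2 <- flows[2:1, ]
  trees2 <- trees[2:1, ]
  trees2$species <- c("zz", "aa")[match(trees2$species, c("s2", "s1"))]
  expect_equal(upscale_sapflow(flows2, trees2, 10, 800)$e_t, 2.5)

  # missing basal area drops the row with a warning
  trees3 <- rbind(trees, data.frame(tree_id = "c", species = "s1", A_b = NA))
  flows3 <- rbind(flows, data.frame(date = as.Date("2000-01-01"),
                                    tree_id = "c", sap_cm3_h = 5))
  expect_warning(out <- upscale_sapflow(flows3, trees3, 10, 800), "dropped")
  expect_equal(out$e_t, 2.5)
})

test_that("seasonal anomalies vanish for constant and repeating series", {
  dates <- as.Date("2001-01-01") + 0:729
  expect_equal(seasonal_anomaly(rep(3, 730), dates), rep(0, 730))
  doy <- as.integer(format(dates, "%j"))
  sinus <- sin(2 * pi * doy / 365)
  an <- seasonal_anomaly(sinus, dates)
  expect_lt(max(abs(an)), 0.02)
  expect_error(seasonal_anomaly(1:100, dates[1:100]), "full year")
})

test_that("an additive spike is recovered as its own anomaly", {
  dates <- as.Date("2001-01-01") + 0:(4 * 365 - 1)
  doy <- as.integer(format(dates, "%j"))
  base <- 10 + 5 * cos(2 * pi * doy / 365)
  x <- base
  x[500] <- x[500] + 4
  an <- seasonal_anomaly(x, dates)
  # the spike leaks into the climatology by ~ spike / (n_years * window)
  expect_equal(an[500], 4, tolerance = 0.05)
  expect_lt(max(abs(an[-500])), 0.2)
})

test_that("per-day-of-year anomaly means are near zero", {
  dates <- as.Date("2001-01-01") + 0:(3 * 365 - 1)
  set.seed(2)
  doy <- as.integer(format(dates, "%j"))
  x <- 8 + 4 * sin(2 * pi * doy / 365) + rnorm(length(dates), sd = 0.5)
  an <- seasonal_anomaly(x, dates)
  per_doy <- tapply(an, doy, mean)
  expect_lt(max(abs(per_doy)), 0.8)
  expect_lt(abs(mean(an)), 0.05)
})

test_that("the training table recovers truth exactly on a noise-free world", {
  f <- generate_forcing(10, 730)
  obs <- generate_observations(f, truth_stress_spec(noise_sd = 0),
                               soil_params("short"), seed = 3, c_canopy = 0)
  tab <- build_training_table(obs)
  expect_equal(tab$s_t, tab$s_t_true, tolerance = 1e-12)
  expect_equal(names(tab)[3:14], covariate_schema())
  expect_gt(attr(tab, "n_rain_removed"), 0)
})

test_that("potential scaling then the stress ratio recovers truth on a world that transpires at potential after rain", {
  # world built to satisfy the assumption behind the bias correction:
  # the truth saturates to 1 for moist soil, substantial rain wets the
  # shallow column enough that every post-rain day sits at stress 1
  cl <- default_climate(rain_p01 = 0.25, rain_p11 = 0.5, rain_mean = 12)
  f <- generate_forcing(21, 1461, cl)
  sp <- soil_params("short", depths = c(50, 200))
  tr <- truth_stress_spec("paw_only", noise_sd = 0,
                          params = list(paw_sat = 0.3))
  obs <- generate_observations(f, tr, sp, seed = 4, c_canopy = 0,
                               rain_threshold = 5)
  # precondition: the world satisfies the transpire-at-potential assumption
  expect_true(all(obs$s_t_true[obs$post_rain] == 1))
  expect_gt(sum(obs$post_rain), 50)

  tab <- build_training_table(obs, scale_ept = TRUE, rain_threshold = 5)
  expect_gt(sd(tab$s_t_true), 0.1)  # targets vary: dry-downs do occur
  expect_equal(tab$s_t, tab$s_t_true, tolerance = 1e-12)
  expect_equal(kge(tab$s_t, tab$s_t_true)$kge, 1, tolerance = 1e-9)
})
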