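test_that("plant-available water scales between wilting point and critical moisture", {
  p <- soil_params("short", w_wp = 0.1, w_c = 0.3)
  expect_equal(compute_paw(0.1, p), 0)
  expect_equal(compute_paw(0.3, p), 1)
  expect_equal(compute_paw(0.2, p), 0.5)
  # clamped outside the range
  expect_equal(compute_paw(0.05, p), 0)
  expect_equal(compute_paw(0.4, p), 1)
  # non-decreasing in w_w
  ww <- seq(0.05, 0.45, by = 0.01)
  expect_true(all(diff(compute_paw(ww, p)) >= 0))
})

test_that("degenerate soil parameters are rejected", {
  expect_error(soil_params("short", w_wp = 0.3, w_c = 0.3), "w_wp < w_c")
  expect_error(soil_params("short", w_r = 0.2, w_wp = 0.1), "w_r < w_wp")
  expect_error(soil_params("tall", depths = c(100, -5, 10)), "positive")
})

test_that("a day with no rain and no demand leaves the column unchanged", {
  p <- soil_params("tall")
  s <- soil_state_init(p, w = c(0.2, 0.25, 0.3))
  out <- step_water_balance(s, P = 0, E_t = 0, E_b = 0, params = p)
  expect_equal(out$state$w, s$w)
  expect_equal(out$drainage, 0)
})

test_that("rain on a saturated column drains through entirely", {
  p <- soil_params("short")
  s <- soil_state_init(p, w = p$porosity)
  out <- step_water_balance(s, P = 12.5, E_t = 0, E_b = 0, params = p)
  expect_equal(out$drainage, 12.5)
  expect_equal(out$state$w, s$w)
})

test_that("extraction is capped at water available above residual moisture", {
  p <- soil_params("short", depths = c(50, 100))
  s <- soil_state_init(p, w = c(0.06, 0.07))
  avail <- (0.06 - p$w_r) * 50 + 0  # wettest layer is layer 2 for E_t
  out <- step_water_balance(s, P = 0, E_t = 100, E_b = 100, params = p)
  expect_lt(out$E_t, 100)
  expect_lt(out$E_b, 100)
  expect_gt(out$shortfall, 0)
  expect_true(all(out$state$w >= p$w_r - 1e-12))
})

test_that("a year of random forcing closes the water balance to 1e-6 mm", {
  p <- soil_params("tall")
  s <- soil_state_init(p, w = 0.25)
  set.seed(42)
  total_in <- total_out <- 0
  s0 <- soil_storage(s, p)
  for (d in 1:365) {
    P <- if (runif(1) < 0.3) rexp(1, 1 / 8) else 0
    out <- step_water_balance(s, P = P, E_t = runif(1, 0, 4),
                              E_b = runif(1, 0, 1), params = p)
    total_in <- total_in + P
    total_out <- total_out + out$E_t + out$E_b + out$drainage
    s <- out$state
  }
  expect_lt(abs(total_in - total_out - (soil_storage(s, p) - s0)), 1e-6)
})

test_that("layer moistures stay within [w_r, porosity] over many random steps", {
  p <- soil_params("short")
  s <- soil_state_init(p, w = 0.25)
  set.seed(7)
  lo <- hi <- TRUE
  for (i in 1:10000) {
    out <- step_water_balance(s, P = rexp(1, 1 / 5) * (runif(1) < 0.3),
                              E_t = runif(1, 0, 6), E_b = runif(1, 0, 2),
                              params = p)
    s <- out$state
    lo <- lo && all(s$w >= p$w_r - 1e-12)
    hi <- hi && all(s$w <= p$porosity + 1e-12)
  }
  expect_true(lo)
  expect_true(hi)
})

test_that("more rain never leaves any layer drier, all else equal", {
  p <- soil_params("tall")
  set.seed(3)
  for (i in 1:50) {
    w0 <- runif(3, p$w_r, p$porosity)
    s <- soil_state_init(p, w = w0)
    e_t <- runif(1, 0, 4); e_b <- runif(1, 0, 1)
    p1 <- runif(1, 0, 10); p2 <- p1 + runif(1, 0, 10)
    out1 <- step_water_balance(s, P = p1, E_t = e_t, E_b = e_b, params = p)
    out2 <- step_water_balance(s, P = p2, E_t = e_t, E_b = e_b, params = p)
    expect_true(all(out2$state$w >= out1$state$w - 1e-12))
  }
})
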