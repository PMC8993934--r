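test_that("the training objective hits its analytic anchors", {
  expect_equal(kge_objective(c(1, 2, 3), c(1, 2, 3)), 0)
  # constant prediction at the target mean: r := 0, alpha = 0, beta = 1
  expect_equal(kge_objective(rep(2, 4), c(1, 2, 3, 2)), sqrt(2))
  expect_equal(kge_objective(c(2, 3, 4), c(1, 2, 3)), 0.5)
  expect_error(kge_objective(c(1, 2), c(3, 3)), "zero variance")
})

test_that("objective and evaluation-module KGE agree to 1e-12", {
  set.seed(8)
  for (i in 1:100) {
    obs <- rnorm(40, mean = 4)
    sim <- obs * runif(1, 0.3, 1.8) + rnorm(40, sd = 0.4)
    expect_equal(kge_objective(sim, obs), 1 - kge(sim, obs)$kge,
                 tolerance = 1e-12)
  }
})

test_that("training is deterministic given a seed", {
  tab <- tiny_training_table()
  m1 <- train_stress_model(tab, quick_mlp_config(seed = 4))
  m2 <- train_stress_model(tab, quick_mlp_config(seed = 4))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_stress_model(tab, quick_mlp_config(seed = 5))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("predictions are bounded, batch-consistent and schema-checked", {
  m <- train_stress_model(tiny_training_table(), quick_mlp_config())
  set.seed(12)
  X <- matrix(rnorm(1e5 * 12, sd = 3), ncol = 12,
              dimnames = list(NULL, covariate_schema()))
  p <- predict(m, X)
  expect_true(all(p >= 0 & p <= 1))
  # batch prediction equals row-by-row prediction
  small <- X[1:25, , drop = FALSE]
  loop <- vapply(seq_len(25), function(i) {
    predict(m, small[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(predict(m, small), loop)
  bad <- X[1:5, ]
  colnames(bad) <- rev(covariate_schema())
  expect_error(predict(m, bad), "schema")
})

test_that("model bundles round-trip through the on-disk format", {
  m <- train_stress_model(tiny_training_table(), quick_mlp_config())
  path <- withr::local_tempdir()
  save_stress_model(m, file.path(path, "bundle"))
  m2 <- load_stress_model(file.path(path, "bundle"))
  X <- as.matrix(tiny_training_table()[1:50, covariate_schema()])
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-8)
  expect_equal(m2$val_kge, m$val_kge, tolerance = 1e-10)
  expect_true(file.exists(file.path(path, "bundle", "history.csv")))
})

test_that("training rejects unusable tables", {
  tab <- tiny_training_table(n = 30)
  expect_error(train_stress_model(tab, quick_mlp_config()), "rows")
  tab2 <- tiny_training_table()
  tab2$paw[5] <- NA
  expect_error(train_stress_model(tab2, quick_mlp_config()), "missing")
})

test_that("a noise-free truth table is learned to validation KGE >= 0.95", {
  world <- generate_world(303, n_sites = 16, n_years = 6,
                          truth = truth_stress_spec(noise_sd = 0))
  tab <- build_training_table(world$sites)
  set.seed(14)
  if (nrow(tab) > 20000) tab <- tab[sort(sample.int(nrow(tab), 20000)), ]
  m <- train_stress_model(tab, mlp_config(seed = 6))
  expect_gte(m$val_kge, 0.95)
})

test_that("the learned model reproduces the truth response to plant-available water", {
  m <- default_stress_model()
  tab <- default_world_table()
  med <- vapply(tab[, covariate_schema()], median, numeric(1))
  transect <- as.data.frame(as.list(med))[rep(1, 41), ]
  transect$paw <- seq(0, 1, by = 0.025)
  transect$paw_anom <- transect$paw - med["paw"]
  pred <- predict(m, transect)
  truth <- truth_stress(truth_stress_spec(), transect$paw, med["vpd"],
                        med["ta"], med["swi"], med["vod"], med["co2"])
  expect_gte(cor(pred, truth, method = "spearman"), 0.95)
})
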