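# Shared fixtures built in code. The default synthetic world and the model
# trained on it are expensive, so they are built lazily once per test run
# and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# default synthetic world: 40 sites x 6 years, noise sd 0.05 on observed E,
# training table subsampled to 50,000 rows
default_world_table <- function() {
  fixture("tab50k", {
    world <- generate_world(101, n_sites = 40, n_years = 6)
    tab <- build_training_table(world$sites)
    set.seed(11)
    if (nrow(tab) > 50000) tab <- tab[sort(sample.int(nrow(tab), 50000)), ]
    tab
  })
}

# stress network trained on the default world with the default protocol
default_stress_model <- function() {
  fixture("model50k", train_stress_model(default_world_table(),
                                         mlp_config(seed = 5)))
}

# an independent world drawn from the same generating process,
# never seen in training
holdout_world_table <- function() {
  fixture("tab_holdout", {
    world <- generate_world(202, n_sites = 6, n_years = 6)
    build_training_table(world$sites)
  })
}

# small quick-training configuration for determinism/contract tests
quick_mlp_config <- function(seed = 1) {
  mlp_config(hidden = c(8, 8), max_epochs = 15, patience = 5,
             batch_size = 50, seed = seed, min_rows = 50)
}

# tiny covariate table with analytic structure for quick training runs
tiny_training_table <- function(n = 400, seed = 99) {
  set.seed(seed)
  tab <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(runif(n * 12), n, 12)), covariate_schema()))
  tab$s_t <- clamp_unit(0.2 + 0.6 * tab$paw)
  tab
}

clamp_unit <- function(x) pmin(1, pmax(0, x))
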