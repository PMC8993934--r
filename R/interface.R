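#' Default pipeline configuration
#'
#' Nested configuration covering every pipeline stage. Any subset of these
#' keys may appear in a YAML config file; unknown keys are rejected on load
#' and missing keys fall back to these defaults.
#'
#' @return a nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    world = list(n_sites = 40L, n_years = 6L, veg_class = "short",
                 noise_sd = 0.05, n_rows = 50000L),
    soil = list(w_wp = 0.15, w_c = 0.30, w_r = 0.05, porosity = 0.45),
    training = list(partition = FALSE, scale_ept = FALSE,
                    rain_threshold = 0.5, ept_min = 0.1,
                    anomaly_window = 31L),
    model = list(hidden = c(64L, 64L, 64L), dropout = 0.1, lr = 0.000142,
                 batch_size = 100L, max_epochs = 1000L, train_frac = 0.85,
                 patience = 20L, min_rows = 500L),
    run = list(alpha = 1.26, c_canopy = 0.5, use_interception = TRUE,
               n_days = 730L, f_tall = 0, f_short = 0.8, f_bare = 0.2,
               f_water = 0)),
    class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop_arg("unknown configuration key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.list(user[[key]])) {
      stop_arg("configuration key ", full, " must be a section")
    }
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      value <- user[[key]]
      if (is.numeric(defaults[[key]]) && !is.numeric(value)) {
        stop_arg("configuration key ", full, " must be numeric")
      }
      if (is.logical(defaults[[key]]) && !is.logical(value)) {
        stop_arg("configuration key ", full, " must be logical")
      }
      defaults[[key]] <- value
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, checks every key against the [default_config()]
#' schema (unknown keys and type mismatches are errors) and fills omitted
#' keys with their defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_arg("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- structure(merge_config(unclass(cfg), user),
                     class = "pipeline_config")
  }
  cfg
}

config_soil <- function(cfg, veg_class) {
  soil_params(veg_class, w_wp = cfg$soil$w_wp, w_c = cfg$soil$w_c,
              w_r = cfg$soil$w_r, porosity = cfg$soil$porosity)
}

write_provenance <- function(cfg, out_dir, stage) {
  rec <- list(stage = stage,
              config_hash = fnv1a_hash(paste(deparse(unclass(cfg)),
                                             collapse = "")),
              seed = cfg$seed,
              package_version = as.character(packageVersion("hybridevap")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, file.path(out_dir, paste0("provenance_", stage,
                                                      ".json")),
                       auto_unbox = TRUE)
  invisible(rec)
}

#' Pipeline stages: generate, prepare, train, run, evaluate
#'
#' Each stage reads and writes only its declared artifacts under `out_dir`
#' and records a provenance file (configuration hash, seed, versions).
#' `pipeline_generate` writes per-site observation tables
#' (`site_<id>.csv`); `pipeline_prepare` writes the supervised training
#' table (`training_table.csv`) and its feature schema
#' (`training_schema.json`); `pipeline_train` writes the model bundle
#' (`stress_model/`); `pipeline_run` writes daily coupled-model output in
#' hybrid and process modes (`run_hybrid.csv`, `run_process.csv`);
#' `pipeline_evaluate` writes per-site skill metrics
#' (`metrics.csv`, `metrics.json`). `pipeline_all` chains all five.
#'
#' @param cfg a validated [load_config()] configuration.
#' @param out_dir artifact directory (created if needed).
#' @return the main artifact of the stage, invisibly.
#' @export
pipeline_generate <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- truth_stress_spec(noise_sd = cfg$world$noise_sd)
  world <- generate_world(cfg$seed, n_sites = cfg$world$n_sites,
                          n_years = cfg$world$n_years, truth = truth,
                          veg_class = cfg$world$veg_class)
  for (s in world$sites) {
    write.csv(s, file.path(out_dir, paste0("site_", s$site_id[1], ".csv")),
              row.names = FALSE)
  }
  write_provenance(cfg, out_dir, "generate")
  invisible(world)
}

#' @rdname pipeline_generate
#' @export
pipeline_prepare <- function(cfg, out_dir) {
  files <- list.files(out_dir, pattern = "^site_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L) stop_arg("no site tables found in ", out_dir)
  sites <- lapply(files, function(f) {
    s <- read.csv(f)
    s$date <- as.Date(s$date)
    s
  })
  tab <- build_training_table(sites, partition = cfg$training$partition,
                              veg_class = cfg$world$veg_class,
                              scale_ept = cfg$training$scale_ept,
                              rain_threshold = cfg$training$rain_threshold,
                              ept_min = cfg$training$ept_min,
                              anomaly_window = cfg$training$anomaly_window)
  if (nrow(tab) > cfg$world$n_rows) {
    set.seed(derive_seed(cfg$seed, "table-subsample"))
    tab <- tab[sort(sample.int(nrow(tab), cfg$world$n_rows)), ]
  }
  write.csv(tab, file.path(out_dir, "training_table.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(features = covariate_schema(),
         target = "s_t",
         units = list(paw = "-", vpd = "kPa", ta = "degC", swi = "W/m2",
                      vod = "-", co2 = "ppm",
                      anomalies = "departure from smoothed day-of-year climatology")),
    file.path(out_dir, "training_schema.json"), auto_unbox = TRUE)
  write_provenance(cfg, out_dir, "prepare")
  invisible(tab)
}

#' @rdname pipeline_generate
#' @export
pipeline_train <- function(cfg, out_dir) {
  path <- file.path(out_dir, "training_table.csv")
  if (!file.exists(path)) stop_arg("training table not found: ", path)
  tab <- read.csv(path)
  mcfg <- mlp_config(hidden = cfg$model$hidden, dropout = cfg$model$dropout,
                     lr = cfg$model$lr, batch_size = cfg$model$batch_size,
                     max_epochs = cfg$model$max_epochs,
                     train_frac = cfg$model$train_frac,
                     patience = cfg$model$patience,
                     seed = derive_seed(cfg$seed, "train"),
                     min_rows = cfg$model$min_rows)
  model <- train_stress_model(tab, mcfg, veg_class = cfg$world$veg_class)
  save_stress_model(model, file.path(out_dir, "stress_model"))
  write_provenance(cfg, out_dir, "train")
  invisible(model)
}

#' @rdname pipeline_generate
#' @export
pipeline_run <- function(cfg, out_dir) {
  model <- load_stress_model(file.path(out_dir, "stress_model"))
  forcing <- generate_forcing(derive_seed(cfg$seed, "run-forcing"),
                              cfg$run$n_days)
  site <- site_meta("RUN", veg_class = cfg$world$veg_class,
                    f_tall = cfg$run$f_tall, f_short = cfg$run$f_short,
                    f_bare = cfg$run$f_bare, f_water = cfg$run$f_water)
  soil_par <- list(tall = config_soil(cfg, "tall"),
                   short = config_soil(cfg, "short"),
                   bare = config_soil(cfg, "bare"))
  params <- run_params(vod_max = compute_vodmax(forcing$VOD),
                       alpha = cfg$run$alpha, c_canopy = cfg$run$c_canopy,
                       use_interception = cfg$run$use_interception)
  models <- list(tall = model, short = model)
  hybrid <- run_model(forcing, site, mode = "hybrid", models = models,
                      params = params, soil_par = soil_par)
  process <- run_model(forcing, site, mode = "process", params = params,
                       soil_par = soil_par)
  write.csv(hybrid, file.path(out_dir, "run_hybrid.csv"), row.names = FALSE)
  write.csv(process, file.path(out_dir, "run_process.csv"),
            row.names = FALSE)
  write_provenance(cfg, out_dir, "run")
  invisible(list(hybrid = hybrid, process = process))
}

#' @rdname pipeline_generate
#' @export
pipeline_evaluate <- function(cfg, out_dir) {
  model <- load_stress_model(file.path(out_dir, "stress_model"))
  files <- list.files(out_dir, pattern = "^site_.*\\.csv$",
                      full.names = TRUE)
  tab <- read.csv(file.path(out_dir, "training_table.csv"))
  rows <- lapply(split(tab, tab$site_id), function(st) {
    pred <- predict(model, st)
    k <- kge(pred, st$s_t)
    tibble::tibble(site_id = st$site_id[1], class = cfg$world$veg_class,
                   kge = k$kge, r = k$r, alpha = k$alpha, beta = k$beta,
                   rmse = rmse(pred, st$s_t), n = k$n)
  })
  metrics <- do.call(rbind, rows)
  summary <- summarize_by_class(metrics)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(list(per_site = metrics, by_class = summary),
                       file.path(out_dir, "metrics.json"), digits = NA,
                       auto_unbox = TRUE)
  write_provenance(cfg, out_dir, "evaluate")
  invisible(list(metrics = metrics, summary = summary))
}

#' @rdname pipeline_generate
#' @export
pipeline_all <- function(cfg, out_dir) {
  pipeline_generate(cfg, out_dir)
  pipeline_prepare(cfg, out_dir)
  pipeline_train(cfg, out_dir)
  pipeline_run(cfg, out_dir)
  pipeline_evaluate(cfg, out_dir)
}
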