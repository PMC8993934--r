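#' Configuration of the learned stress network
#'
#' Defaults follow the training protocol of the stress model: batch size
#' 100, learning rate 0.000142 (Adam), at most 1000 epochs, an 85:15
#' train:validation split pooled across sites, and early stopping when the
#' validation objective (1 - KGE over the full validation set) stops
#' improving for `patience` epochs, with the best weights restored. The
#' default architecture is three hidden layers of 64 ReLU units with
#' dropout 0.1 and a sigmoid output bounding predictions to \[0, 1\].
#'
#' @param hidden integer vector of hidden layer sizes.
#' @param dropout dropout rate on hidden activations during training.
#' @param lr learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param train_frac fraction of rows used for training (rest validates).
#' @param patience early-stopping patience, epochs.
#' @param seed RNG seed for the split, weight init, shuffling and dropout.
#' @param min_rows minimum number of training-table rows accepted.
#' @return a list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(64, 64, 64), dropout = 0.1,
                       lr = 0.000142, batch_size = 100, max_epochs = 1000,
                       train_frac = 0.85, patience = 20, seed = 1,
                       min_rows = 500) {
  if (any(hidden < 1)) stop_arg("hidden layer sizes must be positive")
  if (train_frac <= 0 || train_frac >= 1) {
    stop_arg("train_frac must be in (0, 1)")
  }
  structure(as.list(environment()), class = "mlp_config")
}

#' Training objective: one minus the Kling-Gupta efficiency
#'
#' Set-level loss `1 - KGE(pred, target)`, zero exactly when the prediction
#' reproduces the target. Computed from first principles (sample sd,
#' `r := 0` for a zero-variance prediction) so it can serve as an
#' independent check of the evaluation-module [kge()].
#'
#' @param pred prediction series (>= 2 points).
#' @param target target series with nonzero variance and nonzero mean.
#' @return the scalar loss.
#' @export
#' @examples
#' kge_objective(c(2, 3, 4), c(1, 2, 3)) # 0.5
kge_objective <- function(pred, target) {
  if (length(pred) != length(target) || length(target) < 2L) {
    stop_arg("pred and target must be matched series of >= 2 points")
  }
  n <- length(target)
  mt <- sum(target) / n
  mp <- sum(pred) / n
  st <- sqrt(sum((target - mt)^2) / (n - 1))
  sp <- sqrt(sum((pred - mp)^2) / (n - 1))
  if (st == 0) stop_arg("target has zero variance in this scope")
  if (mt == 0) stop_arg("target has zero mean in this scope")
  r <- if (sp == 0) 0 else {
    sum((pred - mp) * (target - mt)) / ((n - 1) * sp * st)
  }
  sqrt((r - 1)^2 + (sp / st - 1)^2 + (mp / mt - 1)^2)
}

#' Train the feed-forward stress network
#'
#' Trains one network per call (one model per vegetation class) on a
#' training table with the [covariate_schema()] features and an `s_t`
#' target in \[0, 1\]. Rows are split at random into training and validation
#' pools (pooled across sites); features are standardised with
#' training-pool moments; mini-batch gradients use the batch-level 1 - KGE
#' while the early-stopping criterion is the full-set validation objective.
#' Training is deterministic given the seed and single-threaded execution.
#'
#' @param table data frame with the 12 [covariate_schema()] columns and a
#'   numeric `s_t` column; no missing feature values allowed.
#' @param cfg an [mlp_config()].
#' @param veg_class label stored on the model (`"short"` or `"tall"`).
#' @return an object of class `stress_model_mlp` with elements `weights`,
#'   `biases`, `feature_names`, `schema_hash`, `center`, `scale`,
#'   `veg_class`, `config`, `history` (per-epoch train/validation
#'   objective), `val_kge` and `epochs_run`.
#' @export
train_stress_model <- function(table, cfg = mlp_config(),
                               veg_class = "short") {
  feats <- covariate_schema()
  if (!all(feats %in% names(table))) {
    stop_arg("training table lacks covariates: ",
             paste(setdiff(feats, names(table)), collapse = ", "))
  }
  if (!"s_t" %in% names(table)) stop_arg("training table lacks target s_t")
  X <- as.matrix(table[, feats])
  y <- table$s_t
  if (anyNA(X) || anyNA(y)) stop_arg("missing values in features or target")
  if (nrow(X) < cfg$min_rows) {
    stop_arg("training table has ", nrow(X), " rows; at least ",
             cfg$min_rows, " required")
  }

  set.seed(as.integer(cfg$seed))
  n <- nrow(X)
  idx <- sample.int(n)
  n_train <- floor(cfg$train_frac * n)
  tr <- idx[seq_len(n_train)]
  va <- idx[(n_train + 1):n]

  center <- colMeans(X[tr, , drop = FALSE])
  scale <- apply(X[tr, , drop = FALSE], 2, sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  fit <- .mlp_train_cpp(Xs[tr, , drop = FALSE], y[tr],
                        Xs[va, , drop = FALSE], y[va],
                        as.integer(cfg$hidden),
                        cfg$lr, as.integer(cfg$batch_size),
                        as.integer(cfg$max_epochs),
                        cfg$dropout, as.integer(cfg$patience))
  if (isTRUE(fit$diverged)) {
    stop_arg("training aborted: non-finite objective encountered ",
             "(inspect the learning rate and the target distribution)")
  }
  hist <- tibble::tibble(epoch = seq_len(nrow(fit$history)),
                         train_loss = fit$history[, 1],
                         val_loss = fit$history[, 2])
  structure(list(weights = fit$weights,
                 biases = fit$biases,
                 feature_names = feats,
                 schema_hash = fnv1a_hash(paste(feats, collapse = ",")),
                 center = center, scale = scale,
                 veg_class = veg_class,
                 config = cfg,
                 history = hist,
                 val_kge = 1 - fit$best_val_loss,
                 epochs_run = fit$epochs_run),
            class = "stress_model_mlp")
}

#' @export
print.stress_model_mlp <- function(x, ...) {
  cat(sprintf(
    "learned stress model (%s vegetation): %s hidden units, %d epochs, validation KGE %.4f\n",
    x$veg_class, paste(x$config$hidden, collapse = "x"),
    x$epochs_run, x$val_kge))
  invisible(x)
}

#' Predict transpiration stress from covariates
#'
#' Pure function of the inputs; the sigmoid output bounds predictions to
#' \[0, 1\]. The covariate schema of `newdata` must match the schema the
#' model was trained on.
#'
#' @param object a `stress_model_mlp`.
#' @param newdata data frame with the [covariate_schema()] columns, or a
#'   numeric matrix with those column names.
#' @param ... unused.
#' @return numeric vector of stress predictions in \[0, 1\].
#' @export
predict.stress_model_mlp <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (!all(object$feature_names %in% names(newdata))) {
      stop_arg("newdata lacks covariates: ",
               paste(setdiff(object$feature_names, names(newdata)),
                     collapse = ", "))
    }
    newdata <- as.matrix(newdata[, object$feature_names])
  }
  if (is.null(colnames(newdata)) ||
      fnv1a_hash(paste(colnames(newdata), collapse = ",")) !=
        object$schema_hash) {
    stop_arg("covariate schema mismatch: model expects ",
             paste(object$feature_names, collapse = ", "))
  }
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.numeric(.mlp_predict_cpp(Xs, object$weights, object$biases))
}

#' Save / load a trained stress model as a plain-text bundle
#'
#' The bundle is a directory holding `model.json` (weights, feature schema,
#' standardisation moments, configuration) and `history.csv` (per-epoch
#' train and validation objective).
#'
#' @param model a `stress_model_mlp`.
#' @param path bundle directory (created if needed).
#' @return `save_stress_model` returns `path` invisibly;
#'   `load_stress_model` returns the restored `stress_model_mlp`.
#' @export
save_stress_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    weights = lapply(model$weights, unclass),
    biases = lapply(model$biases, as.numeric),
    feature_names = model$feature_names,
    schema_hash = model$schema_hash,
    center = as.list(model$center),
    scale = as.list(model$scale),
    veg_class = model$veg_class,
    config = unclass(model$config),
    val_kge = model$val_kge,
    epochs_run = model$epochs_run)
  jsonlite::write_json(payload, file.path(path, "model.json"),
                       digits = NA, auto_unbox = TRUE)
  write.csv(model$history, file.path(path, "history.csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname save_stress_model
#' @export
load_stress_model <- function(path) {
  p <- jsonlite::read_json(file.path(path, "model.json"),
                           simplifyVector = TRUE)
  hist <- tibble::as_tibble(read.csv(file.path(path, "history.csv")))
  cfg <- p$config
  class(cfg) <- "mlp_config"
  structure(list(weights = lapply(p$weights, as.matrix),
                 biases = lapply(p$biases, as.numeric),
                 feature_names = p$feature_names,
                 schema_hash = p$schema_hash,
                 center = unlist(p$center),
                 scale = unlist(p$scale),
                 veg_class = p$veg_class,
                 config = cfg,
                 history = hist,
                 val_kge = p$val_kge,
                 epochs_run = p$epochs_run),
            class = "stress_model_mlp")
}

#' Process-formula stress predictor
#'
#' Wraps the process-based stress function [process_st()] behind the same
#' predictor interface the coupler uses for the learned model, so a hybrid
#' run with this predictor reproduces a fully process-based run exactly.
#'
#' @param params a [soil_params()] object.
#' @param vod_max upper reference VOD.
#' @return an object of class `stress_model_process`.
#' @export
process_stress_model <- function(params, vod_max) {
  structure(list(params = params, vod_max = vod_max),
            class = "stress_model_process")
}

#' Constant stress predictor
#'
#' Fixed stress factor behind the predictor interface; useful for
#' sensitivity and bookkeeping experiments (e.g. switching transpiration
#' off entirely with `value = 0`).
#'
#' @param value stress factor in \[0, 1\].
#' @return an object of class `stress_model_constant`.
#' @export
constant_stress_model <- function(value) {
  check_number(value, "value", lo = 0, hi = 1)
  structure(list(value = value), class = "stress_model_constant")
}

#' @export
predict_stress.stress_model_constant <- function(model, covariates, aux) {
  model$value
}

#' Evaluate a stress predictor inside the coupled model
#'
#' Dispatch point used by [step_day()]: learned models consume the
#' covariate vector, the process formula consumes VOD and the wettest-layer
#' moisture.
#'
#' @param model a `stress_model_mlp` or `stress_model_process`.
#' @param covariates one-row data frame with the [covariate_schema()]
#'   columns.
#' @param aux list with at least `vod` and `w_w` (used by the process
#'   formula).
#' @return stress factor in \[0, 1\].
#' @export
predict_stress <- function(model, covariates, aux) {
  UseMethod("predict_stress")
}

#' @export
predict_stress.stress_model_mlp <- function(model, covariates, aux) {
  predict(model, covariates)
}

#' @export
predict_stress.stress_model_process <- function(model, covariates, aux) {
  process_st(aux$vod, aux$w_w, model$params, model$vod_max)
}
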