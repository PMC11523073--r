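#' Configuration for the CCS regressor
#'
#' The regressor is a fully connected feed-forward network with an input
#' layer (one node per unmasked descriptor), six hidden layers and a single
#' output node, trained with the Adam optimizer on a mean-absolute-error loss
#' with an 80/20 train/validation split and early stopping.
#'
#' @param hidden_layer_widths Integer widths of the hidden layers
#'   (default six layers: 64, 128, 128, 64, 32, 16).
#' @param activations Per-hidden-layer activation, each `"relu"` or `"gelu"`.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs Maximum training epochs (default 400).
#' @param batch_size Mini-batch size (default 32).
#' @param validation_fraction Held-out fraction in (0, 1) (default 0.2).
#' @param patience Early-stopping patience in epochs on the held-out MAE
#'   (default 40); the best-epoch weights are restored.
#' @param seed Integer seed controlling the split, the weight initialization
#'   and the batch order; training is bit-reproducible given the seed.
#' @param feature_mask Which of the five descriptors to use (default all;
#'   any one can be dropped).
#' @param group_split If `TRUE` and a `species` column is present in the
#'   feature table, the validation split is grouped by species so that no
#'   species contributes conformers to both splits. Default is an instance
#'   split.
#' @return A `ccs_regressor_config` list.
#' @export
ccs_regressor_config <- function(hidden_layer_widths = c(64, 128, 128, 64, 32, 16),
                                 activations = c("relu", "gelu", "relu",
                                                 "gelu", "relu", "relu"),
                                 learning_rate = 1e-3, epochs = 400,
                                 batch_size = 32, validation_fraction = 0.2,
                                 patience = 40, seed = 1,
                                 feature_mask = feature_names(),
                                 group_split = FALSE) {
  stopifnot(length(hidden_layer_widths) >= 1, all(hidden_layer_widths >= 1),
            length(activations) == length(hidden_layer_widths),
            all(activations %in% c("relu", "gelu")),
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1, patience >= 1)
  if (!all(feature_mask %in% feature_names()) || length(feature_mask) < 1) {
    abort("feature_mask must be a non-empty subset of the five descriptors")
  }
  structure(list(
    hidden_layer_widths = as.integer(hidden_layer_widths),
    activations = activations, learning_rate = learning_rate,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    validation_fraction = validation_fraction, patience = as.integer(patience),
    seed = as.integer(seed), feature_mask = feature_mask,
    group_split = isTRUE(group_split)
  ), class = "ccs_regressor_config")
}

#' Train the feed-forward CCS regressor
#'
#' Maps the five molecular descriptors to a CCS label (Angstrom^2). The data
#' are split into training/validation sets by a seeded draw, features (and,
#' internally, labels) are standardized by training-split statistics, and the
#' network is optimized with Adam on the mean absolute error. Training is
#' deterministic given the config seed.
#'
#' @param features A data frame of descriptors (e.g. from [featurize()])
#'   containing the columns of `config$feature_mask`, and optionally
#'   `label_ccs` and `species` columns.
#' @param labels Numeric CCS labels (Angstrom^2, positive); defaults to
#'   `features$label_ccs`.
#' @param config A [ccs_regressor_config()].
#' @return A `ccs_regressor` object with the trained weights, the
#'   standardization statistics, the per-epoch loss history, the held-out
#'   metrics (MAE, mean percent error, R^2) and the held-out
#'   [error_statistics()] used for default CCS filter bands.
#' @export
train_ccs_regressor <- function(features, labels = NULL,
                                config = ccs_regressor_config()) {
  if (is.null(labels)) {
    if (!"label_ccs" %in% names(features)) {
      abort("no labels supplied and no label_ccs column in features")
    }
    labels <- features$label_ccs
  }
  labels <- as.numeric(labels)
  missing_cols <- setdiff(config$feature_mask, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("features lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(features)[config$feature_mask])
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n != length(labels)) abort("features and labels differ in length")
  if (n < 10) abort("need at least 10 training instances")
  if (!all(is.finite(labels))) abort("labels must be finite")
  if (any(labels <= 0)) abort("CCS labels must be positive")
  if (!all(is.finite(X))) abort("features must be finite")
  zero_var <- apply(X, 2, sd) == 0
  if (any(zero_var)) {
    abort(paste0("zero-variance feature(s): ",
                 paste(colnames(X)[zero_var], collapse = ", "),
                 "; drop them via the feature mask"))
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_val <- max(1L, round(config$validation_fraction * n))
  if (config$group_split && "species" %in% names(features)) {
    groups <- sample(unique(as.character(features$species)))
    sizes <- cumsum(table(features$species)[groups])
    take <- groups[seq_len(which(sizes >= n_val)[1])]
    val_idx <- which(features$species %in% take)
  } else {
    val_idx <- sample.int(n, n_val)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) < 2) abort("training split too small")

  x_center <- colMeans(X[tr_idx, , drop = FALSE])
  x_scale <- apply(X[tr_idx, , drop = FALSE], 2, sd)
  if (any(x_scale == 0)) abort("zero-variance feature in the training split")
  y_center <- mean(labels[tr_idx])
  y_scale <- sd(labels[tr_idx])
  if (y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (labels - y_center) / y_scale

  fit <- nn_train(Xs[tr_idx, , drop = FALSE], ys[tr_idx],
                  Xs[val_idx, , drop = FALSE], ys[val_idx],
                  config$hidden_layer_widths, config$activations,
                  config$learning_rate, config$epochs, config$batch_size,
                  config$patience)
  fit$history$train_loss <- fit$history$train_loss * y_scale
  fit$history$val_loss <- fit$history$val_loss * y_scale

  model <- structure(list(
    net = fit$net, activations = config$activations,
    feature_mask = config$feature_mask,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    config = config, history = fit$history, best_epoch = fit$best_epoch,
    n_train = length(tr_idx), n_val = length(val_idx)
  ), class = "ccs_regressor")

  val_pred <- predict(model, X[val_idx, , drop = FALSE])
  model$metrics <- evaluate_predictions(val_pred, labels[val_idx])
  model$error_stats <- error_statistics(val_pred, labels[val_idx])
  model
}

#' Batch-predict CCS values for a feature table
#'
#' Order-preserving, pure function of the model and features; an empty input
#' yields an empty output.
#'
#' @param object A trained `ccs_regressor`.
#' @param features A data frame containing the model's feature columns (or a
#'   numeric matrix with matching columns).
#' @param ... Unused.
#' @return Numeric vector of predicted CCS (Angstrom^2), one per input row.
#' @export
predict.ccs_regressor <- function(object, features, ...) {
  if (is.matrix(features)) {
    if (ncol(features) != length(object$feature_mask)) {
      abort("feature matrix does not match the model's feature mask")
    }
    X <- features
  } else {
    missing_cols <- setdiff(object$feature_mask, names(features))
    if (length(missing_cols) > 0) {
      abort(paste0("features lack the model's column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    X <- as.matrix(as.data.frame(features)[object$feature_mask])
  }
  storage.mode(X) <- "double"
  if (nrow(X) == 0) return(numeric(0))
  if (!all(is.finite(X))) abort("features must be finite")
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  drop(nn_forward(object$net, Xs, object$activations)) * object$y_scale +
    object$y_center
}

#' Regression metrics against reference labels
#'
#' @param predictions,labels Equal-length numeric vectors; labels must be
#'   positive (they divide the percent errors).
#' @return One-row tibble: `n`, `mae` (Angstrom^2), `mean_pct_error` (%),
#'   `r2`.
#' @export
#' @examples
#' evaluate_predictions(c(110, 100), c(100, 100))  # MAE 5, mean % error 5
evaluate_predictions <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0) {
    abort("predictions and labels must be non-empty and of equal length")
  }
  if (any(labels <= 0)) abort("labels must be positive")
  res <- predictions - labels
  tibble::tibble(
    n = length(labels),
    mae = mean(abs(res)),
    mean_pct_error = mean(100 * abs(res) / labels),
    r2 = 1 - sum(res^2) / sum((labels - mean(labels))^2)
  )
}

#' @export
print.ccs_regressor <- function(x, ...) {
  cat("<ccs_regressor> ", paste(c(length(x$feature_mask),
                                  x$config$hidden_layer_widths, 1),
                                collapse = "-"), " network\n", sep = "")
  cat("  features: ", paste(x$feature_mask, collapse = ", "), "\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs (best ", x$best_epoch,
      "), n_train ", x$n_train, ", n_val ", x$n_val, "\n", sep = "")
  m <- x$metrics
  cat(sprintf("  held-out: MAE %.3f A^2, mean %% error %.3f, R^2 %.4f\n",
              m$mae, m$mean_pct_error, m$r2))
  invisible(x)
}

#' @describeIn train_ccs_regressor One row per network layer: width,
#'   activation and parameter count.
#' @param x A `ccs_regressor`.
#' @param ... Unused.
#' @export
tidy.ccs_regressor <- function(x, ...) {
  widths <- c(x$config$hidden_layer_widths, 1L)
  acts <- c(x$activations, "linear")
  tibble::tibble(
    layer = seq_along(widths),
    width = widths,
    activation = acts,
    n_parameters = vapply(seq_along(widths), function(l) {
      length(x$net$W[[l]]) + length(x$net$b[[l]])
    }, integer(1))
  )
}

#' @describeIn train_ccs_regressor One-row model summary with held-out
#'   metrics.
#' @export
glance.ccs_regressor <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_train = x$n_train, n_val = x$n_val,
                   epochs_run = nrow(x$history), best_epoch = x$best_epoch),
    x$metrics[c("mae", "mean_pct_error", "r2")]
  )
}

#' Persist a trained CCS regressor as JSON
#'
#' The model directory format is a single JSON file holding the weights, the
#' standardization statistics and the training configuration; reloading
#' reproduces predictions to better than 1e-6 Angstrom^2.
#'
#' @param model A `ccs_regressor`.
#' @param path Output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_ccs_regressor <- function(model, path) {
  stopifnot(inherits(model, "ccs_regressor"))
  payload <- list(
    format = "ccsfocus_regressor_v1",
    feature_mask = model$feature_mask,
    activations = model$activations,
    hidden_layer_widths = model$config$hidden_layer_widths,
    x_center = unname(model$x_center), x_scale = unname(model$x_scale),
    y_center = model$y_center, y_scale = model$y_scale,
    W = lapply(model$net$W, unname), b = model$net$b,
    best_epoch = model$best_epoch, n_train = model$n_train,
    n_val = model$n_val,
    config = unclass(model$config),
    history = model$history, metrics = model$metrics,
    error_stats = unclass(model$error_stats)
  )
  ok <- try(jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA),
            silent = TRUE)
  if (inherits(ok, "try-error")) abort(paste0("cannot write model to ", path))
  invisible(path)
}

#' @rdname save_ccs_regressor
#' @param path Path to a file written by [save_ccs_regressor()].
#' @return `load_ccs_regressor()` returns the reconstructed `ccs_regressor`.
#' @export
load_ccs_regressor <- function(path) {
  if (!file.exists(path)) abort(paste0("no such model file: ", path))
  payload <- try(jsonlite::read_json(path, simplifyVector = TRUE),
                 silent = TRUE)
  if (inherits(payload, "try-error") || !is.list(payload) ||
      !identical(payload$format, "ccsfocus_regressor_v1")) {
    abort(paste0("corrupt or unrecognized model file: ", path))
  }
  need <- c("feature_mask", "activations", "x_center", "x_scale", "y_center",
            "y_scale", "W", "b")
  if (!all(need %in% names(payload))) {
    abort(paste0("corrupt model file (missing fields): ", path))
  }
  W <- lapply(payload$W, function(w) {
    w <- as.matrix(w); storage.mode(w) <- "double"; w
  })
  b <- lapply(payload$b, as.numeric)
  cfg <- payload$config
  config <- ccs_regressor_config(
    hidden_layer_widths = cfg$hidden_layer_widths,
    activations = cfg$activations, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    validation_fraction = cfg$validation_fraction, patience = cfg$patience,
    seed = cfg$seed, feature_mask = cfg$feature_mask,
    group_split = cfg$group_split
  )
  es <- payload$error_stats
  structure(list(
    net = list(W = W, b = b), activations = payload$activations,
    feature_mask = payload$feature_mask,
    x_center = setNames(as.numeric(payload$x_center), payload$feature_mask),
    x_scale = setNames(as.numeric(payload$x_scale), payload$feature_mask),
    y_center = payload$y_center, y_scale = payload$y_scale,
    config = config, history = tibble::as_tibble(payload$history),
    best_epoch = payload$best_epoch, n_train = payload$n_train,
    n_val = payload$n_val, metrics = tibble::as_tibble(payload$metrics),
    error_stats = structure(list(
      per_item_errors = as.numeric(es$per_item_errors),
      mean_error = es$mean_error, n = as.integer(es$n),
      sem_error = es$sem_error
    ), class = "ccs_error_stats")
  ), class = "ccs_regressor")
}
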