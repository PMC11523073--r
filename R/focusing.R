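#' Batch prediction error statistics
#'
#' Per-prediction fractional errors against reference labels, their mean and
#' the standard error of the mean. These statistics size the CCS filter band:
#' `error_i = |pred_i - label_i| / label_i`, `mean_error = sum(error_i) / N`,
#' `sem_error = sd(error_i) / sqrt(N)` (0 when N = 1).
#'
#' @param predictions,labels Equal-length numeric CCS vectors (Angstrom^2);
#'   labels must be positive.
#' @return A `ccs_error_stats` object with fields `per_item_errors`,
#'   `mean_error`, `n`, `sem_error`.
#' @export
#' @examples
#' error_statistics(c(110, 100), c(100, 100))  # mean 0.05, sem 0.05
error_statistics <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0) {
    abort("predictions and labels must be non-empty and of equal length")
  }
  if (!all(is.finite(predictions)) || !all(is.finite(labels))) {
    abort("predictions and labels must be finite")
  }
  if (any(labels <= 0)) abort("labels must be positive")
  err <- abs(predictions - labels) / labels
  n <- length(err)
  structure(list(
    per_item_errors = err,
    mean_error = mean(err),
    n = n,
    sem_error = if (n == 1) 0 else sd(err) / sqrt(n)
  ), class = "ccs_error_stats")
}

#' Construct error statistics from known summary values
#'
#' Useful when the batch error of a model is known only as a mean and a
#' standard error (e.g. read from a report) rather than from raw
#' prediction/label pairs.
#'
#' @param mean_error Mean fractional error (dimensionless, >= 0).
#' @param sem_error Standard error of the mean fractional error (>= 0).
#' @param n Number of predictions the summary is based on.
#' @return A `ccs_error_stats` object (with empty `per_item_errors`).
#' @export
summary_error_stats <- function(mean_error, sem_error = 0, n = 1L) {
  stopifnot(is.finite(mean_error), mean_error >= 0,
            is.finite(sem_error), sem_error >= 0, n >= 1)
  structure(list(per_item_errors = numeric(0), mean_error = mean_error,
                 n = as.integer(n), sem_error = sem_error),
            class = "ccs_error_stats")
}

#' @export
print.ccs_error_stats <- function(x, ...) {
  cat(sprintf("<ccs_error_stats> n = %d, mean = %.6f, sem = %.6f\n",
              x$n, x$mean_error, x$sem_error))
  invisible(x)
}

#' CCS filter band around a user reference CCS
#'
#' The band is set semiautonomously from the batch error statistics of the
#' regressor at its latest evaluation:
#' `upper = ccs_user * (1 + mean_error + sem_error)` and
#' `lower = ccs_user * (1 - mean_error - sem_error)`, so the band widens
#' monotonically with both statistics and collapses to the point
#' `[ccs_user, ccs_user]` for a zero-error model.
#'
#' @param ccs_user User reference CCS (Angstrom^2, positive), typically an
#'   experimental value.
#' @param stats A `ccs_error_stats` object (from [error_statistics()] or
#'   [summary_error_stats()]).
#' @return A one-row `ccs_filter_band` tibble with columns `ccs_user`,
#'   `lower`, `upper`.
#' @export
#' @examples
#' filter_bounds(180, summary_error_stats(0.02, 0.005))  # [175.5, 184.5]
filter_bounds <- function(ccs_user, stats) {
  stopifnot(inherits(stats, "ccs_error_stats"))
  if (!is.finite(ccs_user) || ccs_user <= 0) abort("ccs_user must be positive")
  half <- stats$mean_error + stats$sem_error
  if (half >= 1) {
    abort("mean_error + sem_error >= 1 would give a nonpositive lower bound")
  }
  tibble::new_tibble(
    tibble::tibble(ccs_user = ccs_user,
                   lower = ccs_user * (1 - half),
                   upper = ccs_user * (1 + half)),
    class = "ccs_filter_band"
  )
}

#' Apply a CCS filter band to an ensemble
#'
#' Retains exactly the conformers whose predicted CCS lies inside the closed
#' band `[lower, upper]`, annotating each with its prediction in `pred_ccs`
#' and preserving input order. With a capacity limit `k`, if more than `k`
#' conformers survive, the `k` with the smallest `|pred - ccs_user|` are kept
#' (ties broken by input order).
#'
#' @param ensemble A [conformer_ensemble()].
#' @param predictions Numeric predicted CCS, one per conformer.
#' @param band A `ccs_filter_band` from [filter_bounds()].
#' @param capacity Optional maximum number of conformers to keep.
#' @return The filtered `conformer_ensemble` (possibly with zero rows).
#' @export
apply_ccs_filter <- function(ensemble, predictions, band, capacity = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            inherits(band, "ccs_filter_band"))
  if (length(predictions) != nrow(ensemble)) {
    abort("need exactly one prediction per conformer")
  }
  keep <- which(predictions >= band$lower & predictions <= band$upper)
  if (!is.null(capacity) && length(keep) > capacity) {
    stopifnot(capacity >= 1)
    nearest <- order(abs(predictions[keep] - band$ccs_user))[seq_len(capacity)]
    keep <- sort(keep[nearest])  # stable: ties already resolved by order()
  }
  out <- ensemble_slice(ensemble, keep)
  out$pred_ccs <- predictions[keep]
  out
}

#' Focus a conformer ensemble around a user CCS
#'
#' The full focusing composition: extract the five descriptors, batch-predict
#' CCS with the trained regressor, derive the filter band from the error
#' statistics (defaulting to the model's held-out statistics from its latest
#' training), and apply the band. The returned ensemble carries a
#' `focus_report` attribute summarizing the run; an ensemble whose
#' predictions all fall outside the band yields an empty (zero-row) result,
#' not an error.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param model A trained [train_ccs_regressor()] model.
#' @param ccs_user User reference CCS (Angstrom^2).
#' @param stats Optional `ccs_error_stats`; defaults to `model$error_stats`.
#' @param capacity Optional capacity limit, see [apply_ccs_filter()].
#' @param probe_radius,points_per_atom Descriptor settings, see [featurize()].
#' @return The focused `conformer_ensemble` with attributes `focus_report`
#'   (list: `n_in`, `n_out`, `band`, `pred_summary`) and `predictions`
#'   (all input predictions, in input order).
#' @export
focus_ensemble <- function(ensemble, model, ccs_user, stats = NULL,
                           capacity = NULL, probe_radius = 1.4,
                           points_per_atom = 960) {
  stopifnot(inherits(model, "ccs_regressor"))
  if (is.null(stats)) stats <- model$error_stats
  feats <- featurize(ensemble, probe_radius = probe_radius,
                     points_per_atom = points_per_atom)
  preds <- predict(model, feats)
  band <- filter_bounds(ccs_user, stats)
  out <- apply_ccs_filter(ensemble, preds, band, capacity = capacity)
  report <- list(
    n_in = nrow(ensemble), n_out = nrow(out),
    band = list(ccs_user = band$ccs_user, lower = band$lower,
                upper = band$upper),
    pred_summary = list(min = min(preds), mean = mean(preds), max = max(preds))
  )
  attr(out, "focus_report") <- report
  attr(out, "predictions") <- preds
  attr(out, "band") <- band
  out
}

#' Focusing report of a focused ensemble
#' @param x The result of [focus_ensemble()].
#' @return The `focus_report` attribute (list).
#' @export
focus_report <- function(x) attr(x, "focus_report")
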