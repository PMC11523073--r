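#' Plot the training history of a CCS regressor
#'
#' Training and validation mean-absolute-error curves per epoch (Angstrom^2,
#' on the original CCS scale), with the restored best epoch marked.
#'
#' @param object A trained `ccs_regressor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccs_regressor <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$history, -"epoch",
                                   names_to = "set", values_to = "mae")
  hist_long$set <- sub("_loss$", "", hist_long$set)
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$mae,
                               color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = "MAE (Å²)", color = NULL,
                  title = "CCS regressor training history") +
    ggplot2::theme_minimal()
}

#' Plot the predicted-CCS distribution of a focused ensemble
#'
#' Histogram of the batch CCS predictions for the full input ensemble, with
#' the filter band (solid) and the user CCS (dashed) marked; the subtitle
#' reports how many conformers survived the filter.
#'
#' @param focused The result of [focus_ensemble()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_ccs_focus <- function(focused, bins = 40) {
  preds <- attr(focused, "predictions")
  band <- attr(focused, "band")
  rep <- focus_report(focused)
  if (is.null(preds) || is.null(band)) {
    abort("plot_ccs_focus expects the result of focus_ensemble()")
  }
  ggplot2::ggplot(tibble::tibble(pred_ccs = preds),
                  ggplot2::aes(x = .data$pred_ccs)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = c(band$lower, band$upper)) +
    ggplot2::geom_vline(xintercept = band$ccs_user, linetype = "dashed") +
    ggplot2::labs(
      x = "predicted CCS (Å²)", y = "conformers",
      title = "CCS focusing",
      subtitle = sprintf("%d of %d conformers inside [%.2f, %.2f] Å²",
                         rep$n_out, rep$n_in, band$lower, band$upper)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a candidate evaluation table
#'
#' Per-species percent CCS error with the 3% acceptance threshold drawn as
#' a dashed line.
#'
#' @param object A `ccsf_evaluation` from [evaluate_candidates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccsf_evaluation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$species <- factor(df$species, levels = df$species)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species,
                                   y = .data$percent_error,
                                   fill = .data$pass_3pct)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32",
                                          `FALSE` = "#c62828")) +
    ggplot2::labs(x = NULL, y = "% CCS error") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
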