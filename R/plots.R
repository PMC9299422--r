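#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ROC curves for an experiment
#'
#' Draws the pooled ROC curve of the two-stage model and, when available, the
#' SVE-burden baseline, annotated with their AUROCs.
#'
#' @param object A `paf_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paf_experiment
#' @export
autoplot.paf_experiment <- function(object, ...) {
  roc_model <- object$roc
  roc_model$model <- "two-stage model"
  curves <- roc_model
  if ("burden" %in% names(object$predictions) &&
    any(!is.na(object$predictions$burden))) {
    keep <- !is.na(object$predictions$burden)
    roc_base <- roc_points(
      object$predictions$burden[keep], object$predictions$label[keep]
    )
    roc_base$model <- "SVE burden"
    curves <- dplyr::bind_rows(curves, roc_base)
  }
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      colour = NULL,
      title = sprintf(
        "Patient-level ROC, setting %d (%s)",
        object$config$setting, object$config$period
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the encoder training curve
#'
#' @param object A trained `segment_encoder`.
#' @param ... Unused.
#' @return A ggplot object of train/validation loss per epoch.
#' @method autoplot segment_encoder
#' @export
autoplot.segment_encoder <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
    names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Epoch", y = "Binary cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot elapsed-time detection rates
#'
#' Detection rate (sensitivity at the chosen cutoff) among pAF patients whose
#' elapsed time from diagnosis to the Holter exam falls above vs below each
#' cutoff.
#'
#' @param experiment A `paf_experiment`.
#' @return A ggplot object.
#' @export
plot_elapsed_rates <- function(experiment) {
  el <- experiment$elapsed
  el$stratum <- ifelse(el$stratum == "gt", "> T", "≤ T")
  ggplot2::ggplot(el, ggplot2::aes(factor(.data$t_months), .data$rate,
    fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Elapsed-time cutoff T (months)", y = "Detection rate", fill = NULL
    ) +
    ggplot2::theme_minimal()
}
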