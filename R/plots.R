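#' Plot an ROC curve
#'
#' @param object a `gc_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gc_roc <- function(object, ...) {
  d <- object$curve |>
    dplyr::mutate(fpr = 1 - .data$specificity) |>
    dplyr::arrange(.data$fpr, .data$sensitivity)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f, positive = %s)", object$auc, object$positive)
    ) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves by group
#'
#' @param object a `gc_survfit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gc_survfit <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, estimate = 1),
      .x
    )) |>
    dplyr::ungroup()
  lab <- if (is.na(object$logrank$p_value)) "" else
    sprintf(" (log-rank p = %.3g)", object$logrank$p_value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Overall survival",
                  colour = object$group,
                  title = paste0("Kaplan-Meier by ", object$group, lab)) +
    ggplot2::theme_minimal()
}

#' Scatter of EMT vs MSI signature scores with classification cutoffs
#'
#' The score-space view of the step-wise classifier: each sample positioned
#' by its EMT and MSI scores, coloured by the assigned subtype, with the
#' two cutoffs drawn as reference lines.
#'
#' @param calls a classification tibble from [classify_subtypes()].
#' @param config a [pipeline_config()] supplying the cutoffs (defaults to
#'   the cutoffs stored on `calls`).
#' @return a ggplot.
#' @export
plot_score_scatter <- function(calls, config = NULL) {
  cuts <- attr(calls, "cutoffs")
  emt_cut <- if (!is.null(config)) config$emt_cutoff else cuts[["emt"]]
  msi_cut <- if (!is.null(config)) config$msi_cutoff else cuts[["msi"]]
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$emt_score, y = .data$msi_score,
                                      colour = .data$subtype)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = emt_cut, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = msi_cut, linetype = "dashed") +
    ggplot2::labs(x = "EMT signature score", y = "MSI signature score",
                  colour = "Subtype") +
    ggplot2::theme_minimal()
}
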