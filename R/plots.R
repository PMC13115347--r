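# ggplot2 figures: gate-dominance distributions and training curves.

#' Plot gate-dominance distributions across conditions
#'
#' Distribution of the per-condition semantic-minus-pose gate difference,
#' grouped by pretraining configuration; the dashed line marks equal
#' weighting. Positive values mean the semantic visual stream dominates,
#' negative values a dominance reversal toward head pose.
#'
#' @param results long results tibble from [run_grid()] (intra-visual stage
#'   must be gated in at least one condition).
#' @return a ggplot object.
#' @export
plot_gate_distribution <- function(results) {
  df <- results |>
    dplyr::filter(.data$vis_fusion == "gated", !is.na(.data$gate_delta)) |>
    dplyr::mutate(pretraining = paste0(ifelse(.data$pt_visual, "V", ""),
                                       ifelse(.data$pt_audio, "A", ""),
                                       ifelse(.data$pt_text, "T", "")),
                  pretraining = ifelse(.data$pretraining == "", "none",
                                       .data$pretraining))
  if (nrow(df) == 0) stopf("no gated intra-visual conditions in results")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pretraining, y = .data$gate_delta)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "pretrained modalities", y = expression(Delta == g[semantic] - g[pose]),
                  title = "Intra-visual gate dominance by pretraining configuration") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss and validation AUC per epoch for one fitted model.
#'
#' @param fit a `fusion_fit`.
#' @return a ggplot object.
#' @export
plot_training_history <- function(fit) {
  df <- tidyr::pivot_longer(fit$history, c("loss", "val_auc"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a statistical report
#'
#' Mean and dispersion of AUC and PR-AUC per fusion strategy at each
#' position.
#'
#' @param object a `stat_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot stat_report
#' @export
autoplot.stat_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$fusion_auc, metric = "AUC"),
    dplyr::mutate(object$fusion_pr_auc, metric = "PR-AUC"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_grid(metric ~ position, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean across conditions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
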