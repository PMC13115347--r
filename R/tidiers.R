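# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted fusion model
#'
#' Returns the per-epoch training history (loss, validation AUC, post-clip
#' gradient norm).
#'
#' @param x a `fusion_fit`.
#' @param ... unused.
#' @return tibble with one row per epoch.
#' @method tidy fusion_fit
#' @export
tidy.fusion_fit <- function(x, ...) x$history

#' One-row summary of a fitted fusion model
#'
#' @param x a `fusion_fit`.
#' @param ... unused.
#' @return tibble: best validation AUC and epoch, epochs run, positive-class
#'   weight, parameter count.
#' @method glance fusion_fit
#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(best_val_auc = x$best_val_auc, best_epoch = x$best_epoch,
                 epochs_run = nrow(x$history), w_pos = x$w_pos,
                 n_params = n_model_params(x$model),
                 loss = x$spec$loss)
}

#' Tidy a statistical report
#'
#' @param x a `stat_report` from [analyze_results()].
#' @param table which table: `"fusion_auc"`, `"fusion_pr_auc"`,
#'   `"pretraining"` or `"gates"`.
#' @param ... unused.
#' @return the requested tibble.
#' @method tidy stat_report
#' @export
tidy.stat_report <- function(x, table = c("fusion_auc", "fusion_pr_auc",
                                          "pretraining", "gates"), ...) {
  x[[match.arg(table)]]
}

#' One-row summary of a statistical report
#'
#' @param x a `stat_report`.
#' @param ... unused.
#' @return tibble with condition count and the extreme fusion / transfer
#'   effects.
#' @method glance stat_report
#' @export
glance.stat_report <- function(x, ...) {
  tibble::tibble(n_conditions = x$n_conditions,
                 max_eta2_auc = max(x$fusion_auc$eta2),
                 max_abs_transfer = max(abs(x$pretraining$delta)),
                 n_gated_conditions = nrow(x$gates))
}
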