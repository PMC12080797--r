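#' Plot a predicted survival curve
#'
#' Step plot of `S(t | x)` over time.
#'
#' @param object A [survival_curve][predict_survival_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability S(t | x)") +
    ggplot2::theme_minimal()
}

#' Plot an autoencoder training log
#'
#' Training and validation loss per epoch, with the best-validation epoch
#' marked.
#'
#' @param object The `log` tibble returned by [train_autoencoder()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ae_training_log <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("epoch", "train_loss", "val_loss")],
    -"epoch", names_to = "split", values_to = "loss"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_epoch"),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "Epoch", y = "Loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold metrics of a cross-validation report
#'
#' One boxplot per metric over the outer folds.
#'
#' @param object A `cv_report` from [run_cross_validation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  metrics <- c("reconstruction", "pfs_mse", "mean_auc",
               "overestimation_pct", "ipcw_concordance")
  df <- tidyr::pivot_longer(object$folds[metrics], dplyr::everything(),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot gene attribution frequencies
#'
#' Bar chart of how often each gene appears among the top genes of the top
#' latent features across folds.
#'
#' @param freq A tibble from [gene_frequency_across_folds()] (or the
#'   `gene_frequency` element of a `cv_report`).
#' @param top_n Show at most this many genes.
#' @return A ggplot object.
#' @export
plot_gene_frequency <- function(freq, top_n = 20L) {
  df <- head(freq, top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene, .data$count),
                                   y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Appearances in top latent features") +
    ggplot2::theme_minimal()
}
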