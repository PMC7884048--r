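#' Kernel-density plot of DEG gene lengths by direction
#'
#' The visual transcription-stress readout: under lesion-driven expression
#' loss the down-regulated density is shifted toward long genes relative to
#' the up-regulated density.
#'
#' @param object A `txs_length_bias` object.
#' @param ... Unused.
#' @return A ggplot of the two length densities on the log10 bp scale.
#' @method autoplot txs_length_bias
#' @export
autoplot.txs_length_bias <- function(object, ...) {
  ggplot2::ggplot(object$kde,
                  ggplot2::aes(x = .data$log10_length, y = .data$density,
                               colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gene length (log10 bp)", y = "density",
                  colour = "DEG direction") +
    ggplot2::theme_minimal()
}

#' Per-animal AUC strip plot by group
#'
#' @param object A `txs_auc` object.
#' @param ... Unused.
#' @return A ggplot of per-animal body-weight AUCs by group.
#' @method autoplot txs_auc
#' @export
autoplot.txs_auc <- function(object, ...) {
  ggplot2::ggplot(object$auc, ggplot2::aes(x = .data$group, y = .data$auc)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "body-weight AUC (log10 g x weeks)") +
    ggplot2::theme_minimal()
}
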