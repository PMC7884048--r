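#' Principal-component variance summary of an expression matrix
#'
#' Samples are the observations: intensities are log2-transformed, each gene is
#' centred (no unit-variance scaling, so abundant genes keep their leverage,
#' matching how array-wide PCA is usually presented), and the sample covariance
#' is eigen-decomposed via [stats::prcomp()]. Variance fractions are the
#' eigenvalues over the total variance.
#'
#' @param expr Genes x samples matrix of strictly positive intensities.
#' @param k Number of components for which sample scores are returned
#'   (default 2); if `k` exceeds the rank it is truncated with a warning.
#' @param log2_transform Set `FALSE` if `expr` is already on a log scale.
#' @return A `txs_pca` object: `variance_fraction` (all components, descending),
#'   `scores` (samples x first-k tibble with `sample_id`), `k`.
#' @export
pca_variance <- function(expr, k = 2, log2_transform = TRUE) {
  if (!is.matrix(expr)) abort("`expr` must be a matrix.")
  if (ncol(expr) < 2) abort("PCA needs >= 2 samples.")
  x <- if (log2_transform) {
    if (any(expr <= 0)) abort("`expr` must be strictly positive for log2.")
    t(log2(expr))
  } else {
    t(expr)
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  total <- sum(ev)
  if (total <= .Machine$double.eps) {
    abort("total variance is zero (all samples identical); PCA undefined.")
  }
  rank <- sum(ev > total * 1e-12)
  if (k > rank) {
    warn(sprintf("k = %d exceeds rank %d; truncating.", k, rank))
    k <- rank
  }
  scores <- as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores$sample_id <- colnames(expr) %||% sprintf("s%d", seq_len(ncol(expr)))
  res <- list(
    variance_fraction = ev[seq_len(rank)] / total,
    scores = dplyr::relocate(scores, "sample_id"),
    k = k
  )
  class(res) <- "txs_pca"
  res
}

#' @export
print.txs_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% (first %d of %d components kept)\n",
              100 * vf[1], if (length(vf) > 1) 100 * vf[2] else NA_real_,
              x$k, length(vf)))
  invisible(x)
}

#' @method tidy txs_pca
#' @export
tidy.txs_pca <- function(x, ...) x$scores

#' @method glance txs_pca
#' @export
glance.txs_pca <- function(x, ...) {
  vf <- x$variance_fraction
  tibble(
    pc1_fraction = vf[1],
    pc2_fraction = if (length(vf) > 1) vf[2] else NA_real_,
    pc12_fraction = sum(vf[seq_len(min(2, length(vf)))]),
    n_components = length(vf)
  )
}

#' @param object A `txs_pca` object.
#' @param design Optional design tibble to colour scores by group.
#' @param ... Unused.
#' @rdname pca_variance
#' @method autoplot txs_pca
#' @export
autoplot.txs_pca <- function(object, design = NULL, ...) {
  d <- object$scores
  if (!is.null(design)) d <- left_join(d, design, by = "sample_id")
  vf <- 100 * object$variance_fraction
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", vf[1]),
      y = sprintf("PC2 (%.0f%%)", if (length(vf) > 1) vf[2] else 0)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(design) && "group" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
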