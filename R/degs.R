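#' Call differentially expressed genes with a moderated two-sample t test
#'
#' Intensities are log2-transformed and compared between two groups with an
#' empirical-Bayes moderated Welch-type t: each group's per-gene variance is
#' shrunk toward that group's cross-gene mean variance with prior degrees of
#' freedom `moderation_prior_df` (d0),
#' `s2* = (d0 * s2_bar + df * s2) / (d0 + df)`, the Satterthwaite degrees of
#' freedom `d` are computed from the shrunken variances, and the reference
#' distribution is Student t with `d + d0` df. `moderation_prior_df = 0`
#' recovers the plain Welch t. P-values are Benjamini-Hochberg adjusted over
#' all genes, and a gene is flagged as a DEG when `q_value < fdr` and its
#' linear fold change `2^|log2fc|` is at least `min_linear_fc`.
#'
#' @param expr Genes x samples matrix of strictly positive linear intensities.
#' @param design Design tibble (`sample_id`, `group`).
#' @param group_a,group_b Group labels; `log2fc` is B minus A.
#' @param fdr FDR cutoff for the DEG flag (default 0.05).
#' @param min_linear_fc Minimum linear fold change (default 1.5).
#' @param moderation_prior_df Prior df d0 of the variance shrinkage (default 4).
#' @return Tibble with one row per gene: `gene_id`, `mean_log2_a`,
#'   `mean_log2_b`, `log2fc`, `t`, `df`, `p_value`, `q_value`, `direction`
#'   ("up" iff `log2fc > 0`), `is_deg`.
#' @export
call_degs <- function(expr, design, group_a, group_b, fdr = 0.05,
                      min_linear_fc = 1.5, moderation_prior_df = 4) {
  assert_design(design)
  if (!is.matrix(expr) || is.null(rownames(expr))) {
    abort("`expr` must be a matrix with gene_id rownames.")
  }
  if (any(!is.finite(expr)) || any(expr <= 0)) {
    abort("`expr` must be strictly positive (log2 is taken internally).")
  }
  a <- group_samples(design, group_a)
  b <- group_samples(design, group_b)
  if (length(a) < 2 || length(b) < 2) {
    abort("both groups need >= 2 samples for a variance estimate.")
  }
  la <- log2(expr[, a, drop = FALSE])
  lb <- log2(expr[, b, drop = FALSE])
  na <- length(a); nb <- length(b)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  s2a <- rowSums((la - ma)^2) / (na - 1)
  s2b <- rowSums((lb - mb)^2) / (nb - 1)
  d0 <- moderation_prior_df
  s2a_s <- (d0 * mean(s2a) + (na - 1) * s2a) / (d0 + na - 1)
  s2b_s <- (d0 * mean(s2b) + (nb - 1) * s2b) / (d0 + nb - 1)
  va <- s2a_s / na; vb <- s2b_s / nb
  se <- sqrt(va + vb)
  tstat <- (mb - ma) / se
  d_sw <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  df <- d_sw + d0
  p <- 2 * pt(-abs(tstat), df)
  q <- p.adjust(p, method = "BH")
  lfc <- mb - ma
  tibble(
    gene_id = rownames(expr),
    mean_log2_a = unname(ma), mean_log2_b = unname(mb), log2fc = unname(lfc),
    t = unname(tstat), df = unname(df), p_value = unname(p), q_value = unname(q),
    direction = if_else(lfc > 0, "up", "down"),
    is_deg = q < fdr & 2^abs(lfc) >= min_linear_fc
  )
}

#' Drop identifiers with ambiguous gene annotation
#'
#' Probe sets (or other identifiers) that map to more than one gene symbol are
#' removed before any gene-length analysis, because an ambiguous probe has no
#' single well-defined length. Order is preserved.
#'
#' @param ids Character vector of identifiers to screen.
#' @param annotation Data frame with columns `id` and `symbol`; one row per
#'   (id, symbol) pair, so multi-mapped ids appear on several rows.
#' @return The subset of `ids` mapping to exactly one symbol, in input order.
#' @export
#' @examples
#' ann <- tibble::tibble(id = c("a", "b", "b", "c"),
#'                       symbol = c("X", "X", "Y", "Z"))
#' filter_ambiguous(c("a", "b", "c"), ann)
filter_ambiguous <- function(ids, annotation) {
  if (!is.data.frame(annotation) ||
      !all(c("id", "symbol") %in% names(annotation))) {
    abort("`annotation` must have columns `id` and `symbol`.")
  }
  missing <- setdiff(ids, annotation$id)
  if (length(missing)) {
    abort(sprintf("id(s) missing from annotation: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  n_sym <- annotation |>
    distinct(.data$id, .data$symbol) |>
    dplyr::count(.data$id, name = "n_symbols")
  keep <- n_sym$id[n_sym$n_symbols == 1]
  ids[ids %in% keep]
}
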