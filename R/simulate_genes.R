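#' Simulate a gene catalog with log-normal gene lengths
#'
#' Draws gene lengths as `round(10^N(mean, sd))`, clamped to a 200 bp floor,
#' mimicking the right-skewed mammalian gene-length distribution (median around
#' 16 kb at the defaults, with a long tail of several-hundred-kb genes that
#' carry the transcription-stress signal).
#'
#' @param n_genes Number of genes (>= 1).
#' @param log10_length_mean Mean of log10 length; default 4.2 (~16 kb median).
#' @param log10_length_sd Standard deviation of log10 length (> 0).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A tibble with columns `gene_id`, `length_bp`.
#' @export
#' @examples
#' simulate_gene_catalog(5, seed = 1)
simulate_gene_catalog <- function(n_genes, log10_length_mean = 4.2,
                                  log10_length_sd = 0.6, seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", min = 1)
  assert_scalar_number(log10_length_sd, "log10_length_sd", min = 0, strict = TRUE)
  n_genes <- as.integer(n_genes)
  lengths <- with_seed(derive_seed(seed, "gene_catalog"), {
    pmax(200, round(10^rnorm(n_genes, log10_length_mean, log10_length_sd)))
  })
  tibble(
    gene_id = sprintf("g%06d", seq_len(n_genes)),
    length_bp = as.integer(lengths)
  )
}

#' Lesion-model parameters for one experimental group
#'
#' The expression simulator assumes transcription-blocking lesions land as a
#' Poisson process along the gene at rate `lambda_per_kb`, and that a single
#' lesion abolishes the transcript, so the mean expression of a gene of length
#' L kb is multiplied by `exp(-lambda * L)` — the simplest mechanism under
#' which lesion likelihood is directly proportional to gene length.
#'
#' @param lambda_per_kb Expected transcription-blocking lesions per kb (>= 0).
#' @param baseline_log2_mean Baseline log2 mean intensity of every gene.
#' @param noise_sd_log2 Per-sample multiplicative noise sd on the log2 scale (> 0).
#' @param prog_de_fraction Fraction of genes given programmed (length-independent)
#'   differential expression in this group, in `[0, 1]`.
#' @param prog_de_log2fc Magnitude of the programmed log2 fold change; each
#'   programmed gene receives a random sign so both DE directions occur.
#' @param n_samples Samples (animals) in the group.
#' @return A `lesion_params` list.
#' @export
lesion_params <- function(lambda_per_kb = 0, baseline_log2_mean = 6,
                          noise_sd_log2 = 0.25, prog_de_fraction = 0,
                          prog_de_log2fc = 1, n_samples = 5L) {
  assert_scalar_number(lambda_per_kb, "lambda_per_kb", min = 0)
  assert_scalar_number(noise_sd_log2, "noise_sd_log2", min = 0, strict = TRUE)
  assert_scalar_number(prog_de_fraction, "prog_de_fraction", min = 0)
  if (prog_de_fraction > 1) abort("`prog_de_fraction` must be in [0, 1].")
  assert_scalar_number(n_samples, "n_samples", min = 1)
  structure(
    list(
      lambda_per_kb = lambda_per_kb, baseline_log2_mean = baseline_log2_mean,
      noise_sd_log2 = noise_sd_log2, prog_de_fraction = prog_de_fraction,
      prog_de_log2fc = prog_de_log2fc, n_samples = as.integer(n_samples)
    ),
    class = "lesion_params"
  )
}

#' Default five-group study scenario
#'
#' The default truth scenario pairs a wild-type and a DNA-repair-deficient
#' (Ercc1-like) genotype with dietary-restriction (DR) and rapamycin arms:
#' the repair-deficient groups carry a lesion rate of `lambda` per kb, DR
#' halves it (`dr_factor`), rapamycin leaves it unchanged, and the intervention
#' groups additionally carry programmed, length-independent expression changes.
#'
#' @param lambda Lesion rate per kb in the repair-deficient control (default 0.004).
#' @param dr_factor Multiplier applied to `lambda` under dietary restriction.
#' @param n_samples Samples per group.
#' @param noise_sd_log2 Per-sample log2 noise sd.
#' @return Named list of [lesion_params()] suitable for [simulate_expression()].
#' @export
default_study_groups <- function(lambda = 0.004, dr_factor = 0.5,
                                 n_samples = 5L, noise_sd_log2 = 0.25) {
  list(
    "WT-Control" = lesion_params(0, n_samples = n_samples,
                                 noise_sd_log2 = noise_sd_log2),
    "WT-DR" = lesion_params(0, prog_de_fraction = 0.10,
                            n_samples = n_samples, noise_sd_log2 = noise_sd_log2),
    "Ercc1-Control" = lesion_params(lambda, prog_de_fraction = 0.05,
                                    n_samples = n_samples,
                                    noise_sd_log2 = noise_sd_log2),
    "Ercc1-Rapa" = lesion_params(lambda, prog_de_fraction = 0.05,
                                 n_samples = n_samples,
                                 noise_sd_log2 = noise_sd_log2),
    "Ercc1-DR" = lesion_params(lambda * dr_factor, prog_de_fraction = 0.10,
                               n_samples = n_samples,
                               noise_sd_log2 = noise_sd_log2)
  )
}

#' Simulate a linear-scale expression matrix under the lesion model
#'
#' For a gene of length L kb in a group with lesion rate lambda, the mean
#' linear intensity is
#' `2^baseline * exp(-lambda * L) * 2^(s * prog_de_log2fc)` where `s` is +1/-1
#' for the group's programmed-DE genes (drawn independently of gene length) and
#' 0 otherwise. Each sample then receives independent multiplicative log-normal
#' noise with sd `noise_sd_log2` on the log2 scale. Sexes alternate F/M within
#' each group.
#'
#' @param catalog Gene catalog from [simulate_gene_catalog()].
#' @param groups Named list of [lesion_params()], one per group (>= 2 groups).
#' @param seed Master seed; per-group substreams are derived with [derive_seed()].
#' @return A list with `expr` (genes x samples matrix, linear scale), `design`
#'   (tibble: sample_id, group, sex) and `truth` (list with `group_lambda`
#'   tibble and `programmed` tibble of gene/group programmed status and sign).
#' @export
simulate_expression <- function(catalog, groups, seed = 1L) {
  assert_catalog(catalog)
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a named list of >= 2 lesion_params.")
  }
  labels <- names(groups)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort("`groups` must have unique, non-empty names.")
  }
  n_genes <- nrow(catalog)
  L_kb <- catalog$length_bp / 1000

  cols <- list()
  design <- list()
  programmed <- list()
  for (lab in labels) {
    p <- groups[[lab]]
    sub <- derive_seed(seed, paste0("expression/", lab))
    block <- with_seed(sub, {
      sign <- integer(n_genes)
      n_prog <- round(p$prog_de_fraction * n_genes)
      if (n_prog > 0) {
        idx <- sample.int(n_genes, n_prog)
        sign[idx] <- ifelse(runif(n_prog) < 0.5, -1L, 1L)
      }
      mu_log2 <- p$baseline_log2_mean - p$lambda_per_kb * L_kb / log(2) +
        sign * p$prog_de_log2fc
      noise <- matrix(rnorm(n_genes * p$n_samples, 0, p$noise_sd_log2),
                      n_genes, p$n_samples)
      list(values = 2^(mu_log2 + noise), sign = sign)
    })
    sample_ids <- sprintf("%s_s%02d", lab, seq_len(p$n_samples))
    colnames(block$values) <- sample_ids
    cols[[lab]] <- block$values
    design[[lab]] <- tibble(
      sample_id = sample_ids, group = lab,
      sex = rep_len(c("F", "M"), p$n_samples)
    )
    programmed[[lab]] <- tibble(
      gene_id = catalog$gene_id, group = lab,
      programmed = block$sign != 0, prog_sign = block$sign
    )
  }
  expr <- do.call(cbind, unname(cols))
  rownames(expr) <- catalog$gene_id
  list(
    expr = expr,
    design = bind_rows(design),
    truth = list(
      group_lambda = tibble(
        group = labels,
        lambda_per_kb = unname(vapply(groups, function(p) p$lambda_per_kb,
                                      numeric(1)))
      ),
      programmed = bind_rows(programmed)
    )
  )
}
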