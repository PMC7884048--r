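# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a text tag
#'
#' All simulators consume one master seed and derive an independent substream
#' seed per operation (and per group) from it, so that adding a group or
#' reordering calls does not perturb unrelated streams. The derivation is a
#' small multiplicative hash over the tag's UTF-8 code points folded into the
#' master seed modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param tag Character scalar naming the substream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "expression")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% m
  s <- ((abs(seed) %% m) * 48271 + h) %% m
  as.integer(max(1, s))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Round half-up to `digits` decimals (printed-ration convention; base round()
# is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict && x <= min) || (!strict && x < min)) {
    abort(sprintf(
      "`%s` must be %s %s.", name, if (strict) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}

assert_catalog <- function(catalog) {
  if (!is.data.frame(catalog) || nrow(catalog) == 0) {
    abort("`catalog` must be a non-empty data frame (gene_id, length_bp).")
  }
  if (!all(c("gene_id", "length_bp") %in% names(catalog))) {
    abort("`catalog` must have columns `gene_id` and `length_bp`.")
  }
  if (anyDuplicated(catalog$gene_id)) abort("`catalog` gene_ids must be unique.")
  if (any(catalog$length_bp < 1)) abort("`catalog` lengths must be >= 1 bp.")
  invisible(catalog)
}

assert_design <- function(design) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "group") %in% names(design))) {
    abort("`design` must be a data frame with columns `sample_id` and `group`.")
  }
  if (anyDuplicated(design$sample_id)) abort("`design` sample_ids must be unique.")
  invisible(design)
}

assert_survival_table <- function(table) {
  need <- c("animal_id", "group", "time_weeks", "event")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    abort(sprintf(
      "survival table must have columns %s.",
      paste0("`", need, "`", collapse = ", ")
    ))
  }
  if (anyDuplicated(table$animal_id)) abort("animal_ids must be unique.")
  if (!all(table$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  if (any(table$time_weeks < 0)) abort("`time_weeks` must be >= 0.")
  invisible(table)
}

group_samples <- function(design, group) {
  ids <- design$sample_id[design$group == group]
  if (length(ids) == 0) abort(sprintf("group '%s' absent from design.", group))
  ids
}
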