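# Internal validation helpers shared across modules.

# Wide expression tibble contract: first column "gene" (character, unique),
# remaining columns numeric sample intensities on the log2 scale.
check_expr <- function(expr, gene_col = "gene", call = rlang::caller_env()) {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort("`expr` must be a data frame with a gene column plus sample columns.",
          call = call)
  }
  if (!gene_col %in% names(expr)) {
    abort(paste0("`expr` must contain a '", gene_col, "' column."), call = call)
  }
  vals <- as.matrix(expr[setdiff(names(expr), gene_col)])
  if (!is.numeric(vals)) {
    abort("All sample columns of `expr` must be numeric.", call = call)
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("Expression values must be finite.", call = call)
  }
  if (anyDuplicated(names(expr))) {
    abort("Duplicate sample IDs in `expr`.", call = call)
  }
  invisible(expr)
}

# Extract the numeric matrix (genes x samples) from a wide expression tibble.
expr_matrix <- function(expr, gene_col = "gene") {
  m <- as.matrix(expr[setdiff(names(expr), gene_col)])
  rownames(m) <- expr[[gene_col]]
  m
}

check_samples <- function(samples, expr = NULL, call = rlang::caller_env()) {
  if (!is.data.frame(samples) || !all(c("sample", "group") %in% names(samples))) {
    abort("`samples` must be a data frame with columns 'sample' and 'group'.",
          call = call)
  }
  if (anyDuplicated(samples$sample)) {
    abort("Duplicate sample IDs in `samples`.", call = call)
  }
  if (!is.null(expr)) {
    missing <- setdiff(samples$sample, setdiff(names(expr), "gene"))
    if (length(missing) > 0) {
      abort(paste0("Samples not present in `expr`: ",
                   paste(missing, collapse = ", ")), call = call)
    }
  }
  invisible(samples)
}

check_seed <- function(seed, call = rlang::caller_env()) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != as.integer(seed)) {
    abort("`seed` must be a single integer.", call = call)
  }
  as.integer(seed)
}

# Percentile with linear interpolation between order statistics (quantile
# type 7), pinned so filter boundaries are reproducible.
percentile <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE)
}
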