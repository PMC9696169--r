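#' Read and write tab-delimited expression matrices
#'
#' The on-disk format is plain TSV: first column `gene` (or `probe_id` for
#' probe-level matrices), header row of sample IDs, log2 intensities.
#'
#' @param path File path.
#' @param gene_col Name of the identifier column (default `"gene"`).
#' @return `read_expression()` returns a wide tibble.
#' @export
read_expression <- function(path, gene_col = "gene") {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!gene_col %in% names(out)) {
    abort(paste0("Expected a '", gene_col, "' column in ", path))
  }
  check_expr(out, gene_col = gene_col)
  out
}

#' @rdname read_expression
#' @param expr Wide expression tibble.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read and write sample-to-group maps
#'
#' Two-column TSV with header `sample`, `group`.
#'
#' @param path File path.
#' @return A tibble with columns `sample`, `group`.
#' @export
read_sample_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_samples(out)
  out
}

#' @rdname read_sample_map
#' @param samples Tibble with columns `sample`, `group`.
#' @export
write_sample_map <- function(samples, path) {
  check_samples(samples)
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' One set per line: name, description, then member symbols, tab-separated.
#' An optional sidecar TSV (columns `signature`, `gene`, `direction`) adds
#' per-member direction labels.
#'
#' @param path GMT file path.
#' @param directions Optional path to the direction sidecar TSV.
#' @return A `gene_signature` tibble with columns `signature`, `gene` and,
#'   when directions are supplied, `direction`.
#' @export
read_gmt <- function(path, directions = NULL) {
  sets <- fgsea::gmtPathways(path)
  out <- tibble::tibble(
    signature = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE)
  )
  if (!is.null(directions)) {
    dir_tab <- readr::read_tsv(directions, show_col_types = FALSE,
                               progress = FALSE)
    if (!all(c("signature", "gene", "direction") %in% names(dir_tab))) {
      abort("Direction sidecar needs columns signature, gene, direction.")
    }
    out <- dplyr::left_join(out, dir_tab, by = c("signature", "gene"))
  }
  class(out) <- c("gene_signature", class(out))
  out
}

#' @rdname read_gmt
#' @param signatures A `gene_signature` tibble (columns `signature`,
#'   `gene`), or a named list of symbol vectors.
#' @param description Description field written for every set (default
#'   `"na"`).
#' @export
write_gmt <- function(signatures, path, description = "na") {
  sets <- if (is.data.frame(signatures)) {
    split(signatures$gene, signatures$signature)
  } else signatures
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write contrast tables
#'
#' TSV with columns `gene`, `log2fc` (or `fc`) and optionally `t`, `p`,
#' `q`; the format used both for this package's results and for external
#' contrasts consumed in cross-comparisons.
#'
#' @param path File path.
#' @param name Contrast label attached to the result (default: file name).
#' @return A tibble of class `contrast_result` (moderation attributes are
#'   not restored from disk).
#' @export
read_contrast <- function(path, name = NULL) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(out)) abort("Contrast table needs a `gene` column.")
  if (!"log2fc" %in% names(out)) {
    if ("fc" %in% names(out)) out$log2fc <- log2(out$fc)
    else abort("Contrast table needs a `log2fc` or `fc` column.")
  }
  if (!"fc" %in% names(out)) out$fc <- 2^out$log2fc
  attr(out, "contrast") <- name %||% sub("\\.[^.]*$", "", basename(path))
  class(out) <- c("contrast_result", class(out))
  out
}

#' @rdname read_contrast
#' @param fit A `contrast_result`.
#' @export
write_contrast <- function(fit, path) {
  keep <- intersect(c("gene", "log2fc", "fc", "t", "p", "q"), names(fit))
  readr::write_tsv(tibble::as_tibble(fit)[keep], path, progress = FALSE)
  invisible(path)
}
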