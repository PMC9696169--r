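#' Collapse probe sets to one row per gene symbol
#'
#' Probes lacking a symbol annotation are dropped; when several probes map to
#' the same symbol ("siblings"), the probe with the highest average intensity
#' across all samples is retained, ties broken by the lexicographically
#' smallest probe ID. If the annotation carries an `is_protein_coding`
#' column, non-coding probes are dropped before collapsing.
#'
#' @param expr Wide probe-level tibble: `probe_id` column plus numeric sample
#'   columns.
#' @param annotation Data frame with columns `probe_id`, `symbol` and
#'   optionally `is_protein_coding` (logical).
#' @return A gene-level tibble (`gene` column plus sample columns) with one
#'   row per symbol, sorted by symbol.
#' @export
collapse_probesets <- function(expr, annotation) {
  check_expr(expr, gene_col = "probe_id")
  if (is.null(annotation) || nrow(annotation) == 0) {
    abort("`annotation` is empty.")
  }
  if (!all(c("probe_id", "symbol") %in% names(annotation))) {
    abort("`annotation` needs columns probe_id and symbol.")
  }
  ann <- tibble::as_tibble(annotation)
  ann <- dplyr::filter(ann, !is.na(.data$symbol), nzchar(.data$symbol))
  if ("is_protein_coding" %in% names(ann)) {
    ann <- dplyr::filter(ann, .data$is_protein_coding)
  }
  sample_cols <- setdiff(names(expr), "probe_id")
  joined <- dplyr::inner_join(expr, ann[c("probe_id", "symbol")], by = "probe_id")
  if (nrow(joined) == 0) abort("No probes remain after annotation join.")
  joined$.mean <- rowMeans(as.matrix(joined[sample_cols]))
  kept <- joined |>
    dplyr::arrange(.data$symbol, dplyr::desc(.data$.mean), .data$probe_id) |>
    dplyr::distinct(.data$symbol, .keep_all = TRUE)
  out <- kept[c("symbol", sample_cols)]
  names(out)[1] <- "gene"
  tibble::as_tibble(out)
}

#' Filter genes by detection above a per-sample intensity percentile
#'
#' A gene is considered detected in a sample when its intensity strictly
#' exceeds the detection threshold; the threshold is the given percentile of
#' that sample's intensities over all genes in the matrix
#' (`scope = "sample"`) or of the pooled intensities of the comparison
#' samples (`scope = "pooled"`). Genes detected in at least
#' `min_detected_samples` of the comparison samples are retained.
#'
#' @param expr Gene-level wide tibble.
#' @param comparison_samples Character vector of sample IDs defining the
#'   comparison; defaults to all samples.
#' @param detection_percentile Percentile in `[0, 100]` defining the
#'   threshold (default 20).
#' @param min_detected_samples Minimum number of comparison samples in which
#'   a gene must be detected (default 2).
#' @param scope `"sample"` (per-sample thresholds, default) or `"pooled"`
#'   (one threshold from the pooled comparison-sample intensities).
#' @param thresholds Optional named numeric vector of detection thresholds
#'   (one per comparison sample), overriding the percentile computation;
#'   the thresholds actually used are attached to the result as the
#'   `"detection_thresholds"` attribute, so a filter can be re-applied with
#'   pinned thresholds (under which it is exactly idempotent).
#' @return The filtered tibble (same columns, subset of rows).
#' @export
filter_detection <- function(expr, comparison_samples = NULL,
                             detection_percentile = 20,
                             min_detected_samples = 2,
                             scope = c("sample", "pooled"),
                             thresholds = NULL) {
  check_expr(expr)
  scope <- match.arg(scope)
  if (detection_percentile < 0 || detection_percentile > 100) {
    abort("`detection_percentile` must be in [0, 100].")
  }
  all_samples <- setdiff(names(expr), "gene")
  comparison_samples <- comparison_samples %||% all_samples
  if (!all(comparison_samples %in% all_samples)) {
    abort("`comparison_samples` must be a subset of the matrix samples.")
  }
  m <- expr_matrix(expr)[, comparison_samples, drop = FALSE]
  if (is.null(thresholds)) {
    thresholds <- if (scope == "sample") {
      apply(expr_matrix(expr), 2, percentile,
            p = detection_percentile)[comparison_samples]
    } else {
      setNames(rep(percentile(as.vector(m), detection_percentile), ncol(m)),
               comparison_samples)
    }
  } else {
    if (!all(comparison_samples %in% names(thresholds))) {
      abort("`thresholds` must be named by comparison sample.")
    }
    thresholds <- thresholds[comparison_samples]
  }
  detected <- sweep(m, 2, thresholds, FUN = ">")
  keep <- rowSums(detected) >= min_detected_samples
  out <- expr[keep, , drop = FALSE]
  attr(out, "detection_thresholds") <- thresholds
  out
}

#' Filter genes with low variation across the comparison samples
#'
#' Computes the per-gene standard deviation over the comparison samples and
#' removes genes whose SD is strictly below the given percentile of the SD
#' distribution.
#'
#' @inheritParams filter_detection
#' @param sd_percentile Percentile in `[0, 100]` of the per-gene SD
#'   distribution below which genes are excluded (default 5).
#' @param sd_cutoff Optional explicit SD cutoff overriding the percentile
#'   computation; the cutoff used is attached as the `"sd_cutoff"`
#'   attribute (re-application with a pinned cutoff is idempotent).
#' @return The filtered tibble.
#' @export
filter_variance <- function(expr, comparison_samples = NULL, sd_percentile = 5,
                            sd_cutoff = NULL) {
  check_expr(expr)
  if (sd_percentile < 0 || sd_percentile > 100) {
    abort("`sd_percentile` must be in [0, 100].")
  }
  all_samples <- setdiff(names(expr), "gene")
  comparison_samples <- comparison_samples %||% all_samples
  if (!all(comparison_samples %in% all_samples)) {
    abort("`comparison_samples` must be a subset of the matrix samples.")
  }
  if (length(comparison_samples) < 2) {
    abort("Need at least 2 comparison samples to compute SDs.")
  }
  m <- expr_matrix(expr)[, comparison_samples, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  cut <- sd_cutoff %||% percentile(sds, sd_percentile)
  out <- expr[sds >= cut, , drop = FALSE]
  attr(out, "sd_cutoff") <- cut
  out
}
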