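#' Pair two contrasts on their shared genes
#'
#' Inner join of two symbol-keyed contrast tables (case-insensitive). The
#' first contrast is treated as the reference (`x`), whose significance
#' flags, when present, are carried along for discordant-gene extraction.
#'
#' @param contrast_x,contrast_y Data frames with columns `gene`, `log2fc`
#'   (a `contrast_result` qualifies); `contrast_x` may carry a `q` column.
#' @param label_x,label_y Source labels (default: contrast attributes).
#' @return A tibble of class `paired_contrast` with columns `gene`,
#'   `log2fc_x`, `log2fc_y` (plus `q_x` when available) and attributes
#'   `label_x`, `label_y`, `n_x`, `n_y`.
#' @export
align_contrasts <- function(contrast_x, contrast_y,
                            label_x = NULL, label_y = NULL) {
  for (d in list(contrast_x, contrast_y)) {
    if (!all(c("gene", "log2fc") %in% names(d))) {
      abort("Contrasts need `gene` and `log2fc` columns.")
    }
  }
  x <- tibble::tibble(key = toupper(contrast_x$gene), gene = contrast_x$gene,
                      log2fc_x = contrast_x$log2fc)
  if ("q" %in% names(contrast_x)) x$q_x <- contrast_x$q
  y <- tibble::tibble(key = toupper(contrast_y$gene), log2fc_y = contrast_y$log2fc)
  paired <- dplyr::inner_join(x, y, by = "key")
  if (nrow(paired) == 0) abort("The two contrasts share no genes.")
  paired$key <- NULL
  attr(paired, "label_x") <- label_x %||% attr(contrast_x, "contrast") %||% "x"
  attr(paired, "label_y") <- label_y %||% attr(contrast_y, "contrast") %||% "y"
  attr(paired, "n_x") <- nrow(contrast_x)
  attr(paired, "n_y") <- nrow(contrast_y)
  class(paired) <- c("paired_contrast", class(paired))
  paired
}

#' Spearman correlation between two contrasts' fold-changes
#'
#' Rank correlation with mid-ranks for ties; two-sided p-value from the t
#' approximation, or the exact permutation distribution for 8 or fewer
#' pairs without ties.
#'
#' @param paired A `paired_contrast`.
#' @return A tibble with columns `rho`, `p`, `n`.
#' @export
spearman_fc <- function(paired) {
  if (nrow(paired) < 3) abort("Need at least 3 pairs.")
  if (sd(paired$log2fc_x) == 0 || sd(paired$log2fc_y) == 0) {
    abort("Correlation undefined: one fold-change vector is constant.")
  }
  n <- nrow(paired)
  has_ties <- anyDuplicated(paired$log2fc_x) || anyDuplicated(paired$log2fc_y)
  res <- suppressWarnings(cor.test(paired$log2fc_x, paired$log2fc_y,
                                   method = "spearman",
                                   exact = n <= 8 && !has_ties))
  tibble::tibble(rho = unname(res$estimate), p = res$p.value, n = n)
}

#' Quadrant proportions of a fold-change scatter
#'
#' Assigns every gene to a quadrant by the signs of its two log2
#' fold-changes. Genes lying exactly on either axis are excluded from the
#' proportions (which sum to 1 over off-axis genes) and counted separately.
#'
#' @param paired A `paired_contrast`.
#' @return A tibble with columns `up_up`, `up_down`, `down_down`,
#'   `down_up`, `n_off_axis`, `n_on_axis` (quadrants named by the signs of
#'   `x` then `y`).
#' @export
quadrant_proportions <- function(paired) {
  if (nrow(paired) < 1) abort("Need at least 1 pair.")
  x <- paired$log2fc_x
  y <- paired$log2fc_y
  on_axis <- x == 0 | y == 0
  if (all(on_axis)) abort("All pairs lie on an axis; quadrants undefined.")
  xs <- x[!on_axis] > 0
  ys <- y[!on_axis] > 0
  n <- sum(!on_axis)
  tibble::tibble(
    up_up = sum(xs & ys) / n,
    up_down = sum(xs & !ys) / n,
    down_down = sum(!xs & !ys) / n,
    down_up = sum(!xs & ys) / n,
    n_off_axis = n,
    n_on_axis = sum(on_axis)
  )
}

#' Central coverage ellipse by Mahalanobis distance
#'
#' Marks the fraction of genes closest to the bivariate centroid of the
#' fold-change scatter: squared Mahalanobis distances to the sample mean
#' under the sample covariance, with the inclusion threshold taken as the
#' empirical coverage quantile so that exactly `ceiling(coverage * n)`
#' points are included (ties broken by original order).
#'
#' @param paired A `paired_contrast`.
#' @param coverage Fraction of genes to include (default 0.90).
#' @return The input with an added logical `in_ellipse` column and
#'   attributes `center` (length-2), `covariance` (2x2), `threshold`
#'   (squared distance at the boundary).
#' @export
mahalanobis_ellipse <- function(paired, coverage = 0.90) {
  if (nrow(paired) < 3) abort("Need at least 3 pairs.")
  if (coverage <= 0 || coverage > 1) abort("`coverage` must be in (0, 1].")
  xy <- cbind(paired$log2fc_x, paired$log2fc_y)
  center <- colMeans(xy)
  covm <- cov(xy)
  if (!is.finite(determinant(covm)$modulus) || det(covm) <= 0) {
    abort("Sample covariance is singular; ellipse undefined.")
  }
  d2 <- mahalanobis(xy, center, covm)
  k <- ceiling(coverage * nrow(xy))
  ord <- rank(d2, ties.method = "first")
  out <- paired
  out$in_ellipse <- ord <= k
  attr(out, "center") <- center
  attr(out, "covariance") <- covm
  attr(out, "threshold") <- sort(d2)[k]
  out
}

#' Genes responding in the direction opposite to a reference contrast
#'
#' Extracts genes significantly regulated in the reference contrast (`x`,
#' flag `q_x < reference_q_max`, sign by `reference_direction`) whose
#' response fold-change (`y`) crosses a threshold in the opposite direction,
#' e.g. genes up-regulated by a reference stimulus but down-regulated by a
#' treatment. Results are sorted by response magnitude.
#'
#' @param paired A `paired_contrast` carrying a `q_x` column.
#' @param reference_direction `"up"` or `"down"`: sign of the reference
#'   response selecting the genes.
#' @param reference_q_max Significance cutoff on `q_x` (default 0.10).
#' @param response_fc_threshold Linear fold-change the response must cross
#'   in the opposite direction (e.g. 0.67 when the reference direction is
#'   up, 1.50 when down).
#' @return A tibble of discordant genes with columns `gene`, `log2fc_x`,
#'   `q_x`, `log2fc_y`, `fc_y`, sorted by `abs(log2fc_y)` descending.
#' @export
discordant_genes <- function(paired, reference_direction = c("up", "down"),
                             reference_q_max = 0.10, response_fc_threshold) {
  reference_direction <- match.arg(reference_direction)
  if (!"q_x" %in% names(paired)) {
    abort("`paired` lacks reference significance flags (q_x).")
  }
  sig <- paired$q_x < reference_q_max
  ref_sign <- if (reference_direction == "up") paired$log2fc_x > 0
              else paired$log2fc_x < 0
  fc_y <- 2^paired$log2fc_y
  opposite <- if (reference_direction == "up") fc_y < response_fc_threshold
              else fc_y > response_fc_threshold
  out <- paired[sig & ref_sign & opposite, , drop = FALSE]
  out <- tibble::as_tibble(out[c("gene", "log2fc_x", "q_x", "log2fc_y")])
  out$fc_y <- 2^out$log2fc_y
  dplyr::arrange(out, dplyr::desc(abs(.data$log2fc_y)))
}
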