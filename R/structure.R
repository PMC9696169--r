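#' Principal component analysis of samples
#'
#' Centers every gene across samples (no unit-variance scaling by default)
#' and decomposes the centered genes-by-samples matrix by SVD. Sample
#' scores, gene loadings, and the fraction of variance explained by each
#' component are returned. The sign of each component is fixed so its
#' largest-magnitude gene loading is positive.
#'
#' @param expr Gene-level wide tibble.
#' @param n_components Number of components to keep (default: all
#'   `min(n_genes, n_samples - 1)` informative components).
#' @param scale. Also scale genes to unit variance (default `FALSE`).
#' @return A list of class `pca_result` with elements `scores` (tibble:
#'   `sample` + `PC*` columns), `loadings` (tibble: `gene` + `PC*`),
#'   `variance_explained` (numeric), `center`, `scale`.
#' @export
pca_scores <- function(expr, n_components = NULL, scale. = FALSE) {
  check_expr(expr)
  m <- expr_matrix(expr)
  if (ncol(m) < 2) abort("Need at least 2 samples.")
  centered <- m - rowMeans(m)
  if (scale.) {
    s <- apply(m, 1, stats::sd)
    if (any(s == 0)) abort("Cannot scale constant genes to unit variance.")
    centered <- centered / s
  }
  max_comp <- min(nrow(m), ncol(m) - 1)
  n_components <- n_components %||% max_comp
  if (n_components > min(dim(m))) {
    abort("`n_components` exceeds the matrix dimensions.")
  }
  sv <- svd(centered)
  total_var <- sum(sv$d^2)
  keep <- seq_len(n_components)
  flip <- vapply(keep, function(j) {
    u <- sv$u[, j]
    if (u[which.max(abs(u))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$u[, keep, drop = FALSE], 2, flip, `*`)
  scores <- sweep(sv$v[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components),
                  2, flip, `*`)
  pc_names <- paste0("PC", keep)
  colnames(scores) <- pc_names
  colnames(loadings) <- pc_names
  structure(
    list(scores = dplyr::bind_cols(tibble::tibble(sample = colnames(m)),
                                   tibble::as_tibble(scores)),
         loadings = dplyr::bind_cols(tibble::tibble(gene = expr$gene),
                                     tibble::as_tibble(loadings)),
         variance_explained = sv$d[keep]^2 / total_var,
         center = TRUE, scale = scale.),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- round(100 * x$variance_explained, 1)
  cat("<pca_result> ", nrow(x$scores), " samples, ",
      length(ve), " components (", paste0(ve, "%", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples from pairwise correlation distance
#' (`1 - Pearson r`, default) or Euclidean distance, with configurable
#' linkage. Samples are ordered by label before clustering so the merge
#' order is deterministic under distance ties.
#'
#' @param expr Gene-level wide tibble.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(expr, distance = c("correlation", "euclidean"),
                                 linkage = "average") {
  check_expr(expr)
  distance <- match.arg(distance)
  m <- expr_matrix(expr)
  m <- m[, order(colnames(m)), drop = FALSE]
  if (ncol(m) < 2) abort("Need at least 2 samples.")
  d <- if (distance == "correlation") {
    as.dist(1 - stats::cor(m))
  } else {
    dist(t(m))
  }
  if (anyNA(d)) abort("Distance matrix contains NaN (constant sample?).")
  hclust(d, method = linkage)
}

#' Export a sample dendrogram in Newick format
#'
#' @param clustering An `hclust` object (see [hierarchical_cluster()]).
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
cluster_newick <- function(clustering, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the 'ape' package.")
  }
  phy <- ape::as.phylo(clustering)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Average principal-component scores per group
#'
#' @param pca A `pca_result`.
#' @param samples Tibble with columns `sample`, `group` covering every
#'   scored sample.
#' @return A tibble with columns `group`, `component`, `mean_score`,
#'   ready for radial plotting.
#' @export
group_pc_profiles <- function(pca, samples) {
  check_samples(samples)
  scores <- pca$scores
  unmapped <- setdiff(scores$sample, samples$sample)
  if (length(unmapped) > 0) {
    abort(paste0("Samples without a group: ", paste(unmapped, collapse = ", ")))
  }
  scores |>
    dplyr::left_join(samples, by = "sample") |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score") |>
    dplyr::group_by(.data$group, .data$component) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
}
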