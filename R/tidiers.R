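#' Tidy a fitted contrast
#'
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @return A plain tibble of the per-gene statistics.
#' @export
tidy.contrast_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "contrast_result")
  tibble::as_tibble(out)
}

#' One-row summary of a fitted contrast
#'
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @return A one-row tibble: contrast label, group sizes, universe size,
#'   moderation state and prior parameters, and DEG-free summary counts of
#'   nominally significant genes.
#' @export
glance.contrast_result <- function(x, ...) {
  tibble::tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_genes = nrow(x),
    n_a = attr(x, "n_a") %||% NA_integer_,
    n_b = attr(x, "n_b") %||% NA_integer_,
    moderated = isTRUE(attr(x, "moderated")),
    d0 = attr(x, "d0") %||% NA_real_,
    s0_sq = attr(x, "s0_sq") %||% NA_real_,
    n_p_below_05 = sum(x$p < 0.05)
  )
}

#' @export
tidy.lsd_result <- function(x, ...) x$pairwise

#' @export
glance.lsd_result <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$groups), mse = x$mse,
                 df_error = x$df_error, alpha = x$alpha,
                 n_letters = length(unique(unlist(strsplit(x$groups$letters, "")))))
}

#' @export
tidy.pca_result <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_components = length(x$variance_explained),
                 total_variance_explained = sum(x$variance_explained))
}
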