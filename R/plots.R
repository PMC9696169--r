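#' Volcano plot of a fitted contrast
#'
#' @param object A `contrast_result` (moderated and adjusted for the
#'   default colouring).
#' @param fc_up,fc_down Fold-change guides (defaults 1.50 / 0.67).
#' @param cutoff Significance cutoff on `q` when present, else on `p`
#'   (default 0.10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contrast_result <- function(object, fc_up = 1.50, fc_down = 0.67,
                                     cutoff = 0.10, ...) {
  sig <- if ("q" %in% names(object)) object$q < cutoff else object$p < cutoff
  d <- tibble::tibble(
    log2fc = object$log2fc,
    neg_log10_p = -log10(pmax(object$p, .Machine$double.xmin)),
    status = dplyr::case_when(
      sig & object$fc > fc_up ~ "increased",
      sig & object$fc < fc_down ~ "decreased",
      TRUE ~ "not called"
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, .data$neg_log10_p,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = log2(c(fc_down, fc_up)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(increased = "#b2182b",
                                            decreased = "#2166ac",
                                            `not called` = "grey70")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 p",
                  title = attr(object, "contrast"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sample score plot for a PCA result
#'
#' @param object A `pca_result`.
#' @param samples Optional sample-to-group map used to colour points.
#' @param components Two components to display (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, samples = NULL,
                                components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  d <- object$scores
  if (!is.null(samples)) d <- dplyr::left_join(d, samples, by = "sample")
  ve <- round(100 * object$variance_explained[components], 1)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]]))
  p <- if (!is.null(samples)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(x = paste0(pcs[1], " (", ve[1], "%)"),
                  y = paste0(pcs[2], " (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Fold-change concordance scatterplot
#'
#' Scatter of paired log2 fold-changes with the quadrant proportions and
#' Spearman correlation annotated and the central Mahalanobis ellipse
#' membership highlighted.
#'
#' @param paired A `paired_contrast`.
#' @param coverage Ellipse coverage (default 0.90).
#' @return A ggplot object.
#' @export
plot_concordance <- function(paired, coverage = 0.90) {
  ell <- mahalanobis_ellipse(paired, coverage)
  quad <- quadrant_proportions(paired)
  rho <- spearman_fc(paired)
  lab <- sprintf("rho = %.2f\n++ %.0f%%  +- %.0f%%\n-- %.0f%%  -+ %.0f%%",
                 rho$rho, 100 * quad$up_up, 100 * quad$up_down,
                 100 * quad$down_down, 100 * quad$down_up)
  ggplot2::ggplot(ell, ggplot2::aes(.data$log2fc_x, .data$log2fc_y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_ellipse),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "goldenrod") +
    ggplot2::annotate("text", x = -Inf, y = Inf, label = lab,
                      hjust = -0.05, vjust = 1.1, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30",
                                            `FALSE` = "#b2182b")) +
    ggplot2::labs(x = attr(paired, "label_x"), y = attr(paired, "label_y"),
                  colour = "central") +
    ggplot2::theme_minimal()
}

#' Kinetic assay time-course plot
#'
#' @param assay Tibble with columns `condition`, `replicate`, `time_min`,
#'   `absorbance`.
#' @return A ggplot object with per-condition least-squares lines.
#' @export
plot_kinetics <- function(assay) {
  ggplot2::ggplot(assay, ggplot2::aes(.data$time_min, .data$absorbance,
                                      colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "time (min)", y = "absorbance (460 nm)") +
    ggplot2::theme_minimal()
}

#' Group means with compact letter display
#'
#' @param object An `lsd_result`.
#' @param ... Unused.
#' @return A ggplot bar chart with letter annotations.
#' @export
autoplot.lsd_result <- function(object, ...) {
  d <- object$groups
  ggplot2::ggplot(d, ggplot2::aes(stats::reorder(.data$group, -.data$mean),
                                  .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + 2 * .data$se,
                                    label = .data$letters), vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}
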