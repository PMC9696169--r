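#' Fit an unmoderated two-group contrast for every gene
#'
#' Per-gene two-sample comparison under a group-mean linear model using only
#' the samples of the two groups involved: `log2fc` is the difference of
#' group means (log2 scale), the residual variance is pooled within groups
#' with `n_a + n_b - 2` degrees of freedom, and the ordinary t-statistic and
#' two-sided p-value are computed from it. Genes with zero pooled variance
#' and zero mean difference get `t = 0, p = 1`.
#'
#' @param expr Gene-level wide tibble (post-filtering).
#' @param samples Tibble with columns `sample`, `group`.
#' @param group_a,group_b Group labels; the contrast is `group_a - group_b`
#'   (so `group_b` is the reference, e.g. `fit_contrast(expr, s, "CYT", "CTL")`).
#' @param name Contrast label (default `"<a> vs <b>"`).
#' @return A tibble of class `contrast_result` with columns `gene`, `log2fc`,
#'   `fc` (linear scale, `2^log2fc`), `mean_expr`, `residual_sd`, `df`, `t`,
#'   `p`, and attributes `contrast`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `moderated` (FALSE).
#' @export
fit_contrast <- function(expr, samples, group_a, group_b,
                         name = paste(group_a, "vs", group_b)) {
  check_expr(expr)
  check_samples(samples, expr)
  sa <- samples$sample[samples$group == group_a]
  sb <- samples$sample[samples$group == group_b]
  if (length(sa) < 2 || length(sb) < 2) {
    abort("Both groups need at least 2 samples.")
  }
  m <- expr_matrix(expr)
  xa <- m[, sa, drop = FALSE]
  xb <- m[, sb, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  df <- na + nb - 2
  s2 <- (ssa + ssb) / df
  log2fc <- ma - mb
  se <- sqrt(s2 * (1 / na + 1 / nb))
  t <- log2fc / se
  t[se == 0 & log2fc == 0] <- 0
  p <- 2 * pt(-abs(t), df = df)
  p[is.infinite(t)] <- 0

  out <- tibble::tibble(
    gene = expr$gene,
    log2fc = unname(log2fc),
    fc = 2^unname(log2fc),
    mean_expr = unname((ma * na + mb * nb) / (na + nb)),
    residual_sd = unname(sqrt(s2)),
    df = df,
    t = unname(t),
    p = unname(p)
  )
  attr(out, "contrast") <- name
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "n_a") <- na
  attr(out, "n_b") <- nb
  attr(out, "moderated") <- FALSE
  class(out) <- c("contrast_result", class(out))
  out
}

# Solve trigamma(x) = y by Newton iteration on the monotone decreasing
# trigamma function; used to invert the second moment of log variances.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Method-of-moments estimation of the variance prior (d0, s0_sq) under the
# scaled-F model for observed residual variances s2 with common df:
# log(s2) has mean log(s0_sq) + digamma(df/2) - log(df/2) - digamma(d0/2) +
# log(d0/2) and excess variance trigamma(d0/2) beyond trigamma(df/2).
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) abort("All residual variances are zero; cannot estimate prior.")
  if (sum(ok) < 10) abort("Need >= 10 genes with positive residual variance.")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Apply empirical-Bayes variance moderation to a fitted contrast
#'
#' Estimates a prior distribution for per-gene residual variances (prior
#' degrees of freedom `d0` and prior variance `s0_sq`) by moment matching of
#' the log residual variances against the scaled-F model, shrinks each
#' gene's variance to the posterior
#' `(d0 * s0_sq + df * s2) / (d0 + df)`, and recomputes t-statistics and
#' p-values with `d0 + df` degrees of freedom (normal reference when `d0`
#' is infinite). `prior_df = 0` leaves the ordinary statistics unchanged;
#' `prior_df = Inf` replaces every variance by the prior variance.
#'
#' @param fit A `contrast_result` from [fit_contrast()].
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (0, positive, or `Inf`).
#' @param prior_var Optional override of the estimated prior variance.
#' @return The `contrast_result` with `t`, `p` replaced by moderated values,
#'   extra columns `t_ordinary`, `s2_post`, and attributes `moderated = TRUE`,
#'   `d0`, `s0_sq`, `df_total`.
#' @export
moderate <- function(fit, prior_df = NULL, prior_var = NULL) {
  if (!inherits(fit, "contrast_result")) {
    abort("`fit` must be a contrast_result from fit_contrast().")
  }
  s2 <- fit$residual_sd^2
  df <- fit$df[1]
  prior <- if (is.null(prior_df) || is.null(prior_var)) {
    estimate_variance_prior(s2, df)
  } else NULL
  d0 <- prior_df %||% prior$d0
  s0_sq <- prior_var %||% prior$s0_sq
  if (d0 < 0) abort("`prior_df` must be non-negative.")

  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  na <- attr(fit, "n_a"); nb <- attr(fit, "n_b")
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t <- fit$log2fc / se
  t[se == 0 & fit$log2fc == 0] <- 0
  df_total <- df + d0
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df_total)
  p[is.infinite(t)] <- 0

  out <- fit
  out$t_ordinary <- fit$t
  out$s2_post <- s2_post
  out$t <- t
  out$p <- p
  attr(out, "moderated") <- TRUE
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_total") <- df_total
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. For a numeric vector of p-values
#' the adjusted q-values are returned in the original order; for a
#' `contrast_result` a `q` column is added.
#'
#' @param x Numeric vector of p-values in `[0, 1]`, or a `contrast_result`.
#' @param ... Unused.
#' @return Adjusted q-values (vector) or the input with a `q` column.
#' @export
adjust_bh <- function(x, ...) UseMethod("adjust_bh")

#' @rdname adjust_bh
#' @export
adjust_bh.numeric <- function(x, ...) {
  if (anyNA(x) || any(x < 0 | x > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(x, method = "BH")
}

#' @rdname adjust_bh
#' @export
adjust_bh.contrast_result <- function(x, ...) {
  x$q <- adjust_bh(x$p)
  x
}

#' Call differentially expressed genes at fold-change and significance cutoffs
#'
#' Applies the joint calling rule: a gene is *increased* when its
#' significance measure is strictly below `cutoff` and its linear
#' fold-change strictly exceeds `fc_up`; *decreased* when significant with
#' fold-change strictly below `fc_down`.
#'
#' @param fit A moderated, FDR-adjusted `contrast_result` (see [moderate()]
#'   and [adjust_bh()]).
#' @param significance_mode `"fdr"` (use the `q` column) or `"raw_p"`.
#' @param cutoff Strict significance cutoff (e.g. 0.10 for FDR mode, 0.05
#'   for raw-p mode).
#' @param fc_up,fc_down Linear fold-change thresholds (defaults 1.50 / 0.67).
#' @return A tibble of class `deg_call` with columns `gene`, `direction`
#'   (`"increased"`/`"decreased"`), `log2fc`, `fc`, `p`, `q`, and attributes
#'   `contrast` and `criteria`.
#' @export
call_degs <- function(fit, significance_mode = c("fdr", "raw_p"), cutoff,
                      fc_up = 1.50, fc_down = 0.67) {
  significance_mode <- match.arg(significance_mode)
  if (!inherits(fit, "contrast_result")) abort("`fit` must be a contrast_result.")
  if (fc_up <= fc_down) abort("`fc_up` must exceed `fc_down`.")
  if (significance_mode == "fdr" && !"q" %in% names(fit)) {
    abort("FDR mode needs a `q` column; run adjust_bh() first.")
  }
  sig <- if (significance_mode == "fdr") fit$q < cutoff else fit$p < cutoff
  up <- sig & fit$fc > fc_up
  down <- sig & fit$fc < fc_down
  out <- dplyr::bind_rows(
    dplyr::mutate(fit[up, ], direction = "increased"),
    dplyr::mutate(fit[down, ], direction = "decreased")
  )
  keep <- intersect(c("gene", "direction", "log2fc", "fc", "p", "q"), names(out))
  out <- tibble::as_tibble(out[keep])
  attr(out, "contrast") <- attr(fit, "contrast")
  attr(out, "criteria") <- list(significance_mode = significance_mode,
                                cutoff = cutoff, fc_up = fc_up,
                                fc_down = fc_down)
  class(out) <- c("deg_call", class(out))
  out
}

#' Genes called in one direction
#'
#' @param call A `deg_call`.
#' @param direction `"increased"` or `"decreased"`.
#' @return Character vector of gene symbols.
#' @export
deg_genes <- function(call, direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  call$gene[call$direction == direction]
}
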