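#' Least-squares absorbance slopes per condition
#'
#' Fits one ordinary least-squares regression of absorbance on time per
#' condition, pooling all replicate wells, with a free intercept. The slope
#' standard error comes from the residual variance of that regression.
#'
#' @param assay Tibble with columns `condition`, `replicate`, `time_min`,
#'   `absorbance` (a `kinetic_assay` qualifies).
#' @return A tibble with columns `condition`, `slope`, `se`, `n_points`.
#' @export
fit_slopes <- function(assay) {
  needed <- c("condition", "time_min", "absorbance")
  if (!all(needed %in% names(assay))) {
    abort("`assay` needs columns condition, time_min, absorbance.")
  }
  if (length(unique(assay$time_min)) < 2) {
    abort("Need at least 2 distinct timepoints.")
  }
  assay |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(absorbance ~ time_min, data = d)
      sm <- suppressWarnings(summary(fit))$coefficients
      tibble::tibble(slope = sm["time_min", "Estimate"],
                     se = sm["time_min", "Std. Error"],
                     n_points = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Percent inhibition relative to a control slope
#'
#' `(1 - treatment_slope / control_slope) * 100`; 0 when the treatment
#' matches the control, 100 when the treatment slope is zero. Negative
#' values (activation) are reported unclipped unless `clip = TRUE`.
#'
#' @param treatment_slope Numeric vector of treatment slopes.
#' @param control_slope Positive control slope (scalar).
#' @param clip Clip negative values to 0 for display (default `FALSE`).
#' @return Numeric vector of percent inhibition values.
#' @export
percent_inhibition <- function(treatment_slope, control_slope, clip = FALSE) {
  if (length(control_slope) != 1 || control_slope <= 0) {
    abort("`control_slope` must be a single positive value.")
  }
  out <- (1 - treatment_slope / control_slope) * 100
  if (clip) out <- pmax(out, 0)
  out
}

#' Two-factor interaction test for a slope difference
#'
#' Fits `absorbance ~ time + condition + time:condition` over the control
#' and treatment series on the same time grid and returns the two-sided
#' t-test p-value for the interaction coefficient, i.e. for the difference
#' between the two slopes.
#'
#' @param assay Tibble with columns `condition`, `time_min`, `absorbance`.
#' @param condition Treatment condition label.
#' @param control Control condition label.
#' @return A tibble with columns `condition`, `slope_difference`, `se`,
#'   `p`.
#' @export
interaction_test <- function(assay, condition, control = "CTL") {
  d <- assay[assay$condition %in% c(condition, control), , drop = FALSE]
  if (!all(c(condition, control) %in% d$condition)) {
    abort("Both conditions must be present in the assay data.")
  }
  d$condition <- factor(d$condition, levels = c(control, condition))
  fit <- lm(absorbance ~ time_min * condition, data = d)
  if (stats::df.residual(fit) < 1) abort("Insufficient residual degrees of freedom.")
  sm <- suppressWarnings(summary(fit))$coefficients
  row <- paste0("time_min:condition", condition)
  tibble::tibble(condition = condition,
                 slope_difference = sm[row, "Estimate"],
                 se = sm[row, "Std. Error"],
                 p = sm[row, "Pr(>|t|)"])
}

#' Slopes, percent inhibition and interaction tests for a whole assay
#'
#' Convenience wrapper combining [fit_slopes()], [percent_inhibition()] and
#' [interaction_test()] against a designated control condition.
#'
#' @param assay Tibble with columns `condition`, `time_min`, `absorbance`.
#' @param control Control condition label (default `"CTL"`).
#' @return A tibble with one row per condition: `condition`, `slope`, `se`,
#'   `pct_inhibition` (NA for the control), `interaction_p` (NA for the
#'   control).
#' @export
inhibition_summary <- function(assay, control = "CTL") {
  slopes <- fit_slopes(assay)
  if (!control %in% slopes$condition) abort("Control condition not found.")
  ctl_slope <- slopes$slope[slopes$condition == control]
  treated <- setdiff(slopes$condition, control)
  inter <- purrr::map_dfr(treated, interaction_test, assay = assay,
                          control = control)
  slopes |>
    dplyr::mutate(
      pct_inhibition = ifelse(.data$condition == control, NA_real_,
                              percent_inhibition(.data$slope, ctl_slope)),
      interaction_p = inter$p[match(.data$condition, inter$condition)]
    )
}

#' Fisher's least-significant-difference test with compact letters
#'
#' One-way ANOVA pooled error variance followed by all pairwise t-tests
#' using the pooled mean squared error and its degrees of freedom. Groups
#' are summarised by a compact letter display in which any two groups
#' sharing a letter do not differ at the given alpha, and every
#' non-significant pair shares at least one letter (letters are the maximal
#' cliques of the non-significance graph, ordered by group mean).
#'
#' @param data Tibble with one measurement per row.
#' @param value,group Column names (strings) of the measurement and group
#'   label (defaults `"value"`, `"group"`).
#' @param alpha Significance level for letter assignment (default 0.05).
#' @return A list of class `lsd_result` with elements `groups` (tibble:
#'   `group`, `n`, `mean`, `se`, `letters`), `pairwise` (tibble: `group1`,
#'   `group2`, `difference`, `p`), `mse`, `df_error`, `alpha`.
#' @export
fisher_lsd <- function(data, value = "value", group = "group", alpha = 0.05) {
  if (!all(c(value, group) %in% names(data))) {
    abort("`data` must contain the value and group columns.")
  }
  v <- data[[value]]
  g <- as.character(data[[group]])
  counts <- table(g)
  if (length(counts) < 2) abort("Need at least 2 groups.")
  if (any(counts < 2)) abort("Every group needs at least 2 replicates.")

  means <- tapply(v, g, mean)
  ns <- as.numeric(counts[names(means)])
  ss_within <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  df_error <- length(v) - length(means)
  mse <- ss_within / df_error

  labs <- names(sort(means, decreasing = TRUE))
  pairs <- utils::combn(labs, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / counts[[a]] + 1 / counts[[b]]))
    tstat <- if (se == 0) {
      if (diff == 0) 0 else Inf * sign(diff)
    } else diff / se
    p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df_error)
    tibble::tibble(group1 = a, group2 = b, difference = unname(diff),
                   p = unname(p))
  })

  letters_tbl <- compact_letters(labs, pw, alpha)
  groups <- tibble::tibble(
    group = labs,
    n = as.integer(counts[labs]),
    mean = as.vector(means[labs]),
    se = sqrt(mse / as.numeric(counts[labs])),
    letters = letters_tbl[labs]
  )
  structure(list(groups = groups, pairwise = pw, mse = mse,
                 df_error = df_error, alpha = alpha),
            class = "lsd_result")
}

# Compact letter display: letters are the maximal cliques of the graph whose
# edges join groups NOT significantly different (p >= alpha). Cliques are
# lettered in order of their best-ranked (highest-mean) member.
compact_letters <- function(labs, pairwise, alpha) {
  adj <- matrix(FALSE, length(labs), length(labs),
                dimnames = list(labs, labs))
  diag(adj) <- TRUE
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$p[i] >= alpha) {
      adj[pairwise$group1[i], pairwise$group2[i]] <- TRUE
      adj[pairwise$group2[i], pairwise$group1[i]] <- TRUE
    }
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  cliques <- lapply(igraph::max_cliques(gr), igraph::as_ids)
  # order cliques by the position of their best member in the mean ranking
  ord <- order(vapply(cliques, function(cl) min(match(cl, labs)), numeric(1)))
  cliques <- cliques[ord]
  out <- setNames(rep("", length(labs)), labs)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  }
  out
}

#' @export
print.lsd_result <- function(x, ...) {
  cat("<lsd_result> Fisher's LSD, pooled MSE = ", signif(x$mse, 4),
      " on ", x$df_error, " df, alpha = ", x$alpha, "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' One-tailed two-sample t-test with pooled variance
#'
#' Pooled-variance two-sample t-test, one-sided in the stated direction
#' (`"greater"` tests mean(a) > mean(b)). With zero pooled variance and
#' equal means the p-value is 0.5 by the symmetry convention.
#'
#' @param a,b Numeric vectors of replicate measurements (each >= 2 values).
#' @param direction `"greater"` or `"less"` for the alternative on
#'   `mean(a) - mean(b)`.
#' @return A tibble with columns `difference`, `t`, `df`, `p`.
#' @export
one_tailed_t <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2) abort("Each group needs >= 2 replicates.")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  diff <- mean(a) - mean(b)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- if (se == 0) {
    if (diff == 0) 0 else Inf * sign(diff)
  } else diff / se
  p <- if (direction == "greater") pt(tstat, df, lower.tail = FALSE)
       else pt(tstat, df, lower.tail = TRUE)
  tibble::tibble(difference = diff, t = tstat, df = df, p = p)
}

#' Blank-normalise plate measurements
#'
#' Subtracts the mean blank (no-tissue control) optical density of each
#' plate from that plate's measurements. Negative corrected values are
#' permitted and flagged.
#'
#' @param data Tibble with columns `plate` and `value`.
#' @param blanks Tibble with columns `plate` and `value` holding blank
#'   measurements for every plate present in `data`.
#' @return `data` with `value` replaced by the corrected value and an added
#'   logical `below_blank` column.
#' @export
normalize_blank <- function(data, blanks) {
  for (d in list(data, blanks)) {
    if (!all(c("plate", "value") %in% names(d))) {
      abort("`data` and `blanks` need columns plate and value.")
    }
  }
  missing <- setdiff(unique(data$plate), unique(blanks$plate))
  if (length(missing) > 0) {
    abort(paste0("No blank for plate(s): ", paste(missing, collapse = ", ")))
  }
  blank_means <- blanks |>
    dplyr::group_by(.data$plate) |>
    dplyr::summarise(.blank = mean(.data$value), .groups = "drop")
  data |>
    dplyr::left_join(blank_means, by = "plate") |>
    dplyr::mutate(value = .data$value - .data$.blank,
                  below_blank = .data$value < 0) |>
    dplyr::select(-".blank")
}
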