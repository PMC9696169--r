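#' Signature members detected in a contrast's tested universe
#'
#' Intersects signature members with the genes of a fitted contrast
#' (case-insensitive symbol match); the returned symbols use the universe's
#' casing.
#'
#' @param signature Character vector of symbols, or a `gene_signature`
#'   tibble (column `gene`).
#' @param fit A `contrast_result`; its `gene` column is the tested universe.
#' @return Character vector of detected members.
#' @export
detect_members <- function(signature, fit) {
  members <- if (is.data.frame(signature)) signature$gene else signature
  universe <- fit$gene
  if (length(universe) == 0) abort("The contrast universe is empty.")
  hit <- match(toupper(unique(members)), toupper(universe))
  universe[hit[!is.na(hit)]]
}

#' Hypergeometric overlap test between a DEG list and a signature
#'
#' Counts genes shared by the DEG list and the detected signature members
#' and computes the upper hypergeometric tail `P(X >= k)` for drawing that
#' many signature members in `|DEG|` draws from a universe containing
#' `|detected|` members.
#'
#' @param deg Character vector of called genes (one direction).
#' @param detected Detected signature members (see [detect_members()]).
#' @param universe_size Number of genes in the tested universe.
#' @return A tibble with columns `n_overlap`, `p`.
#' @export
overlap_test <- function(deg, detected, universe_size) {
  deg <- unique(toupper(deg))
  detected <- unique(toupper(detected))
  if (length(detected) > universe_size || length(deg) > universe_size) {
    abort("DEG list and signature must fit inside the universe.")
  }
  k <- length(intersect(deg, detected))
  p <- phyper(k - 1, m = length(detected),
              n = universe_size - length(detected),
              k = length(deg), lower.tail = FALSE)
  tibble::tibble(n_overlap = k, p = p)
}

# Case-insensitive lookup of fold-changes for signature members.
member_fc <- function(fit, detected, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  idx <- match(toupper(detected), toupper(fit$gene))
  if (anyNA(idx)) abort("Some members are absent from the contrast universe.")
  if (scale == "linear") fit$fc[idx] else fit$log2fc[idx]
}

#' Resampled mean fold-change test
#'
#' Compares a signature's average linear fold-change against the null
#' distribution of the same statistic over random same-size gene sets drawn
#' without replacement from the contrast's tested universe. The empirical
#' p-value uses the add-one estimator `(1 + #{null >= obs}) / (B + 1)` for
#' `alternative = "greater"` (mirrored for `"less"`), so the smallest
#' attainable p is `1 / (B + 1)`.
#'
#' @param fit A `contrast_result`.
#' @param detected Detected signature members.
#' @param alternative `"greater"` (signature FC above random sets) or
#'   `"less"`.
#' @param n_resamples Number of random sets (default 10000).
#' @param seed Integer seed for the resampling.
#' @param scale Average fold-changes on the `"linear"` (default) or
#'   `"log2"` scale.
#' @return A tibble with columns `mean_fc`, `p`, `n_members`, `n_resamples`.
#' @export
resampled_meanfc_test <- function(fit, detected,
                                  alternative = c("greater", "less"),
                                  n_resamples = 10000, seed = 1,
                                  scale = c("linear", "log2")) {
  alternative <- match.arg(alternative)
  scale <- match.arg(scale)
  if (length(detected) < 1) abort("No detected members.")
  if (n_resamples < 1) abort("`n_resamples` must be >= 1.")
  if (length(detected) > nrow(fit)) abort("Signature larger than universe.")
  set.seed(check_seed(seed))
  fc_all <- if (scale == "linear") fit$fc else fit$log2fc
  obs <- mean(member_fc(fit, detected, scale))
  m <- length(unique(toupper(detected)))
  null <- vapply(seq_len(n_resamples),
                 function(i) mean(fc_all[sample.int(length(fc_all), m)]),
                 numeric(1))
  extreme <- if (alternative == "greater") sum(null >= obs) else sum(null <= obs)
  tibble::tibble(mean_fc = obs, p = (1 + extreme) / (n_resamples + 1),
                 n_members = m, n_resamples = as.integer(n_resamples))
}

#' Sign-majority test for a signature's fold-change directions
#'
#' Tests whether signature members are predominantly increased (linear
#' FC > 1) or decreased (FC < 1) with an exact two-sided binomial test
#' against 0.5. Members with FC exactly 1 carry no sign information and are
#' dropped (the count is reported).
#'
#' @inheritParams resampled_meanfc_test
#' @return A tibble with columns `up_fraction`, `p`, `n_informative`,
#'   `n_dropped`.
#' @export
sign_majority_test <- function(fit, detected) {
  fc <- member_fc(fit, detected)
  informative <- fc != 1
  if (!any(informative)) abort("All member fold-changes are exactly 1.")
  n_up <- sum(fc > 1)
  n <- sum(informative)
  p <- binom.test(n_up, n, p = 0.5, alternative = "two.sided")$p.value
  tibble::tibble(up_fraction = n_up / n, p = p,
                 n_informative = n, n_dropped = sum(!informative))
}

#' Rank-enrichment test of a signature within the fold-change ranking
#'
#' One-sided Wilcoxon rank-sum test comparing the fold-change ranks of
#' signature members against all other genes in the universe: `tail = "top"`
#' asks whether members concentrate among the highest fold-changes,
#' `tail = "bottom"` among the lowest. The exact distribution is used for
#' universes of at most 20 genes without ties; otherwise the normal
#' approximation with tie correction.
#'
#' @inheritParams resampled_meanfc_test
#' @param tail `"top"` or `"bottom"`.
#' @return A tibble with columns `p`, `tail`, `n_members`, `n_universe`.
#' @export
rank_enrichment_test <- function(fit, detected, tail = c("top", "bottom")) {
  tail <- match.arg(tail)
  fc_members <- member_fc(fit, detected, scale = "log2")
  others <- setdiff(toupper(fit$gene), toupper(detected))
  if (length(others) == 0) abort("Signature covers the whole universe.")
  fc_others <- fit$log2fc[match(others, toupper(fit$gene))]
  n_univ <- nrow(fit)
  use_exact <- n_univ <= 20 && !anyDuplicated(c(fc_members, fc_others))
  res <- suppressWarnings(wilcox.test(
    fc_members, fc_others,
    alternative = if (tail == "top") "greater" else "less",
    exact = use_exact, correct = FALSE
  ))
  tibble::tibble(p = res$p.value, tail = tail,
                 n_members = length(fc_members), n_universe = n_univ)
}

#' Full enrichment report for one signature against one contrast
#'
#' Combines the four signature statistics: hypergeometric overlap with the
#' increased and decreased DEG lists, resampled mean fold-change, sign
#' majority, and rank enrichment in both tails.
#'
#' @param fit A `contrast_result`.
#' @param degs A `deg_call` for the same contrast, or `NULL` to skip the
#'   overlap tests.
#' @param signature Character vector or `gene_signature` tibble.
#' @param alternative Direction for the resampled mean-FC test.
#' @param n_resamples,seed Resampling settings.
#' @return A one-row tibble (class `enrichment_report`) with columns
#'   `signature`, `contrast`, `n_members`, `n_detected`, `n_overlap_up`,
#'   `overlap_p_up`, `n_overlap_down`, `overlap_p_down`, `mean_fc`,
#'   `resample_p`, `n_resamples`, `sign_up_fraction`, `sign_p`,
#'   `rank_p_top`, `rank_p_bottom`.
#' @export
signature_report <- function(fit, degs, signature,
                             alternative = c("greater", "less"),
                             n_resamples = 10000, seed = 1) {
  alternative <- match.arg(alternative)
  name <- if (is.data.frame(signature) && "signature" %in% names(signature)) {
    signature$signature[1]
  } else "signature"
  members <- if (is.data.frame(signature)) signature$gene else signature
  detected <- detect_members(members, fit)
  universe_size <- nrow(fit)

  if (length(detected) == 0) {
    out <- tibble::tibble(signature = name,
                          contrast = attr(fit, "contrast") %||% NA_character_,
                          n_members = length(unique(members)), n_detected = 0L,
                          n_overlap_up = NA_integer_, overlap_p_up = NA_real_,
                          n_overlap_down = NA_integer_, overlap_p_down = NA_real_,
                          mean_fc = NA_real_, resample_p = NA_real_,
                          n_resamples = as.integer(n_resamples),
                          sign_up_fraction = NA_real_, sign_p = NA_real_,
                          rank_p_top = NA_real_, rank_p_bottom = NA_real_)
    class(out) <- c("enrichment_report", class(out))
    return(out)
  }

  ov_up <- ov_down <- tibble::tibble(n_overlap = NA_integer_, p = NA_real_)
  if (!is.null(degs)) {
    ov_up <- overlap_test(deg_genes(degs, "increased"), detected, universe_size)
    ov_down <- overlap_test(deg_genes(degs, "decreased"), detected, universe_size)
  }
  rs <- resampled_meanfc_test(fit, detected, alternative, n_resamples, seed)
  sg <- sign_majority_test(fit, detected)
  rt <- rank_enrichment_test(fit, detected, "top")
  rb <- rank_enrichment_test(fit, detected, "bottom")

  out <- tibble::tibble(
    signature = name,
    contrast = attr(fit, "contrast") %||% NA_character_,
    n_members = length(unique(members)),
    n_detected = length(detected),
    n_overlap_up = ov_up$n_overlap, overlap_p_up = ov_up$p,
    n_overlap_down = ov_down$n_overlap, overlap_p_down = ov_down$p,
    mean_fc = rs$mean_fc, resample_p = rs$p, n_resamples = rs$n_resamples,
    sign_up_fraction = sg$up_fraction, sign_p = sg$p,
    rank_p_top = rt$p, rank_p_bottom = rb$p
  )
  class(out) <- c("enrichment_report", class(out))
  out
}

#' Directional summaries for a collection of marker panels
#'
#' Runs the resampled mean fold-change and sign-majority tests for each
#' panel (e.g. cell-cycle phases, early/late differentiation markers, a
#' pruritus-associated set) against one contrast. Panels with no detected
#' members are reported as `NA` rows rather than errors.
#'
#' @param fit A `contrast_result`.
#' @param panels Named list of symbol vectors, or a `gene_signature` tibble
#'   with multiple values in its `signature` column.
#' @param alternative Direction for the resampled mean-FC test.
#' @param n_resamples,seed Resampling settings.
#' @return A tibble with one row per panel: `panel`, `n_members`,
#'   `n_detected`, `mean_fc`, `resample_p`, `sign_up_fraction`, `sign_p`.
#' @export
marker_panel_summary <- function(fit, panels,
                                 alternative = c("greater", "less"),
                                 n_resamples = 10000, seed = 1) {
  alternative <- match.arg(alternative)
  if (is.data.frame(panels)) {
    panels <- split(panels$gene, panels$signature)
  }
  if (length(panels) == 0) abort("`panels` is empty.")
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    abort("`panels` must be named.")
  }
  purrr::imap_dfr(panels, function(members, panel_name) {
    detected <- detect_members(members, fit)
    if (length(detected) == 0) {
      return(tibble::tibble(panel = panel_name,
                            n_members = length(unique(members)),
                            n_detected = 0L, mean_fc = NA_real_,
                            resample_p = NA_real_,
                            sign_up_fraction = NA_real_, sign_p = NA_real_))
    }
    rs <- resampled_meanfc_test(fit, detected, alternative, n_resamples, seed)
    sg <- sign_majority_test(fit, detected)
    tibble::tibble(panel = panel_name, n_members = length(unique(members)),
                   n_detected = length(detected), mean_fc = rs$mean_fc,
                   resample_p = rs$p, sign_up_fraction = sg$up_fraction,
                   sign_p = sg$p)
  })
}
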