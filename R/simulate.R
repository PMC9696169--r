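#' Define a synthetic expression experiment
#'
#' Describes a multi-group microarray-style experiment on the log2 scale:
#' group labels, replicate counts, a gene universe, per-gene residual noise
#' drawn from a scaled-inverse-chi-square prior (so that variance-moderation
#' methods have a true prior to recover), and planted group effects.
#'
#' @param group_names Character vector of group labels; the first group is
#'   conventionally the control.
#' @param n_genes Number of genes in the simulated universe.
#' @param replicates_per_group Replicates per group (>= 2).
#' @param baseline_mean Grand mean log2 intensity.
#' @param gene_effect_sd SD of per-gene baseline offsets around
#'   `baseline_mean` (log2 units); models the gene-to-gene intensity spread.
#' @param gene_sd_prior List with elements `d0` (prior degrees of freedom,
#'   may be `Inf` for a constant SD) and `s0` (prior residual SD, log2
#'   units). Per-gene residual variances are drawn as
#'   `d0 * s0^2 / rchisq(d0)`.
#' @param effects Data frame with columns `group`, `gene`, `shift` giving
#'   planted additive log2 shifts, or `NULL` for a null experiment.
#' @param seed Integer seed threaded through all generation.
#'
#' @return An object of class `sim_design`.
#' @seealso [simulate_expression()]
#' @export
sim_design <- function(group_names, n_genes, replicates_per_group = 3,
                       baseline_mean = 7, gene_effect_sd = 1.5,
                       gene_sd_prior = list(d0 = 4, s0 = 0.25),
                       effects = NULL, seed = 1) {
  if (length(group_names) < 1 || anyDuplicated(group_names)) {
    abort("`group_names` must be non-empty and unique.")
  }
  if (!is.numeric(n_genes) || n_genes < 1) {
    abort("`n_genes` must be >= 1.")
  }
  if (!is.numeric(replicates_per_group) || replicates_per_group < 2) {
    abort("`replicates_per_group` must be >= 2.")
  }
  if (!is.list(gene_sd_prior) || !all(c("d0", "s0") %in% names(gene_sd_prior)) ||
      gene_sd_prior$d0 <= 0 || gene_sd_prior$s0 < 0) {
    abort("`gene_sd_prior` must be list(d0 > 0, s0 >= 0).")
  }
  genes <- sprintf("G%06d", seq_len(n_genes))
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    if (!all(c("group", "gene", "shift") %in% names(effects))) {
      abort("`effects` needs columns group, gene, shift.")
    }
    if (!all(effects$group %in% group_names)) {
      abort("`effects` refers to unknown groups.")
    }
    if (!all(effects$gene %in% genes)) {
      abort("`effects` refers to genes outside the simulated universe.")
    }
  }
  structure(
    list(group_names = as.character(group_names),
         n_genes = as.integer(n_genes),
         replicates_per_group = as.integer(replicates_per_group),
         baseline_mean = baseline_mean,
         gene_effect_sd = gene_effect_sd,
         gene_sd_prior = gene_sd_prior,
         effects = effects,
         genes = genes,
         seed = check_seed(seed)),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design> ", x$n_genes, " genes, ",
      length(x$group_names), " groups x ", x$replicates_per_group,
      " replicates\n", sep = "")
  cat("  groups: ", paste(x$group_names, collapse = ", "), "\n", sep = "")
  cat("  planted effects: ",
      if (is.null(x$effects)) 0L else nrow(x$effects), "\n", sep = "")
  invisible(x)
}

#' Simulate a log2 expression matrix with known ground truth
#'
#' Generates `value = baseline_g + shift_{g,group} + N(0, sd_g)` for every
#' gene and sample, where `baseline_g` varies around the design's grand mean,
#' planted shifts come from the design's effect table, and `sd_g` is drawn
#' from the scaled-inverse-chi-square prior. Deterministic given the design
#' seed.
#'
#' @param design A [sim_design()].
#' @return A list of class `sim_experiment` with elements
#'   \describe{
#'     \item{expr}{wide tibble: `gene` column plus one numeric column per sample}
#'     \item{samples}{tibble with columns `sample`, `group`}
#'     \item{truth}{tibble of planted shifts (`group`, `gene`, `shift`)}
#'     \item{gene_params}{tibble `gene`, `baseline`, `sd` of generating values}
#'     \item{design}{the input design}
#'   }
#' @export
simulate_expression <- function(design) {
  if (!inherits(design, "sim_design")) abort("`design` must be a sim_design.")
  set.seed(design$seed)
  genes <- design$genes
  n <- design$n_genes
  groups <- design$group_names
  reps <- design$replicates_per_group

  baseline <- design$baseline_mean + rnorm(n, 0, design$gene_effect_sd)
  d0 <- design$gene_sd_prior$d0
  s0 <- design$gene_sd_prior$s0
  gene_sd <- if (is.infinite(d0)) rep(s0, n) else sqrt(d0 * s0^2 / rchisq(n, d0))

  shift <- matrix(0, nrow = n, ncol = length(groups),
                  dimnames = list(genes, groups))
  if (!is.null(design$effects)) {
    idx <- cbind(match(design$effects$gene, genes),
                 match(design$effects$group, groups))
    shift[idx] <- shift[idx] + design$effects$shift
  }

  sample_ids <- as.vector(vapply(groups, function(g) paste(g, seq_len(reps), sep = "_"),
                                 character(reps)))
  sample_groups <- rep(groups, each = reps)
  mu <- baseline + shift[, sample_groups, drop = FALSE]
  noise <- matrix(rnorm(n * length(sample_ids)), nrow = n) * gene_sd
  values <- mu + noise
  colnames(values) <- sample_ids

  expr <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(values))
  truth <- if (is.null(design$effects)) {
    tibble::tibble(group = character(), gene = character(), shift = numeric())
  } else {
    tibble::as_tibble(design$effects)
  }
  structure(
    list(expr = expr,
         samples = tibble::tibble(sample = sample_ids, group = sample_groups),
         truth = truth,
         gene_params = tibble::tibble(gene = genes, baseline = baseline,
                                      sd = gene_sd),
         design = design),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment> ", nrow(x$expr), " genes x ",
      nrow(x$samples), " samples; ", nrow(x$truth),
      " planted effects\n", sep = "")
  invisible(x)
}

# True per-gene contrast shifts (group_a minus group_b) implied by planted
# effects; genes absent from the table have shift 0.
true_contrast_shifts <- function(truth, group_a, group_b) {
  sh <- function(g) {
    tab <- truth[truth$group == g, c("gene", "shift")]
    setNames(tab$shift, tab$gene)
  }
  a <- sh(group_a); b <- sh(group_b)
  genes <- union(names(a), names(b))
  out <- setNames(numeric(length(genes)), genes)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  out[out != 0]
}

#' Construct a signature concordant and/or discordant with planted effects
#'
#' Builds a direction-labelled gene set from a simulated experiment's ground
#' truth for one contrast. Concordant members are planted differentially
#' expressed genes labelled with their true direction; discordant members are
#' planted genes labelled with the opposite direction; neutral members are
#' non-differential genes with balanced direction labels.
#'
#' @param experiment A `sim_experiment`.
#' @param group_a,group_b Groups defining the contrast (a minus b) whose
#'   planted shifts the signature refers to.
#' @param n_concordant,n_discordant,n_neutral Member counts by category.
#' @param name Signature name.
#' @param seed Integer seed.
#' @return A tibble of class `gene_signature` with columns `signature`,
#'   `gene`, `direction` and attribute `category` recording construction.
#' @export
simulate_signature <- function(experiment, group_a, group_b,
                               n_concordant, n_discordant = 0, n_neutral = 0,
                               name = "synthetic_signature", seed = 1) {
  if (!inherits(experiment, "sim_experiment")) {
    abort("`experiment` must be a sim_experiment.")
  }
  set.seed(check_seed(seed))
  shifts <- true_contrast_shifts(experiment$truth, group_a, group_b)
  de_genes <- names(shifts)
  neutral_pool <- setdiff(experiment$expr$gene, de_genes)

  if (n_concordant + n_discordant > length(de_genes)) {
    abort(paste0("Requested ", n_concordant + n_discordant,
                 " planted members but only ", length(de_genes),
                 " planted DE genes exist for this contrast."))
  }
  if (n_neutral > length(neutral_pool)) {
    abort("Not enough non-differential genes for the requested neutral members.")
  }
  planted <- sample(de_genes, n_concordant + n_discordant)
  conc <- planted[seq_len(n_concordant)]
  disc <- planted[setdiff(seq_along(planted), seq_len(n_concordant))]
  neut <- sample(neutral_pool, n_neutral)

  dir_of <- function(g) unname(ifelse(shifts[g] > 0, "increased", "decreased"))
  flip <- c(increased = "decreased", decreased = "increased")
  neut_dir <- rep(c("increased", "decreased"), length.out = n_neutral)
  if (n_neutral > 0) neut_dir <- sample(neut_dir)

  out <- tibble::tibble(
    signature = name,
    gene = c(conc, disc, neut),
    direction = c(if (length(conc)) dir_of(conc) else character(),
                  if (length(disc)) unname(flip[dir_of(disc)]) else character(),
                  neut_dir)
  )
  attr(out, "category") <- rep(c("concordant", "discordant", "neutral"),
                               c(length(conc), length(disc), length(neut)))
  class(out) <- c("gene_signature", class(out))
  out
}

#' Simulate a kinetic absorbance assay with planted inhibition
#'
#' Generates linear-in-time absorbance series,
#' `A(t) = intercept + ctl_slope * (1 - inhibition) * t + N(0, noise_sd)`,
#' for a control condition plus named treated conditions, emulating an
#' enzyme-activity plate read at fixed intervals.
#'
#' @param ctl_slope Control rate of absorbance increase (absorbance/min, > 0).
#' @param inhibition Named numeric vector of inhibition fractions in `[0, 1]`,
#'   one per treated condition.
#' @param timepoints Strictly increasing read times in minutes.
#' @param n_replicates Replicate wells per condition.
#' @param noise_sd SD of the Gaussian read noise (>= 0).
#' @param intercept Baseline absorbance at time zero.
#' @param control Label for the control condition.
#' @param plate Plate/batch label.
#' @param seed Integer seed.
#' @return A tibble of class `kinetic_assay` with columns `condition`,
#'   `replicate`, `time_min`, `absorbance`, `plate`, and attribute
#'   `truth` (tibble of generating slopes per condition).
#' @export
simulate_kinetic_assay <- function(ctl_slope, inhibition,
                                   timepoints = c(0, 5, 10, 15),
                                   n_replicates = 3, noise_sd = 0.01,
                                   intercept = 0.05, control = "CTL",
                                   plate = "P1", seed = 1) {
  if (is.null(names(inhibition)) || any(!nzchar(names(inhibition)))) {
    abort("`inhibition` must be a named vector of conditions.")
  }
  if (any(inhibition < 0 | inhibition > 1)) {
    abort("Inhibition fractions must lie in [0, 1].")
  }
  if (any(diff(timepoints) <= 0)) abort("`timepoints` must be strictly increasing.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  set.seed(check_seed(seed))

  slopes <- c(setNames(ctl_slope, control), ctl_slope * (1 - inhibition))
  grid <- tidyr::expand_grid(condition = names(slopes),
                             replicate = seq_len(n_replicates),
                             time_min = timepoints)
  grid$absorbance <- intercept + slopes[grid$condition] * grid$time_min +
    rnorm(nrow(grid), 0, noise_sd)
  grid$plate <- plate
  attr(grid, "truth") <- tibble::tibble(condition = names(slopes),
                                        slope = unname(slopes))
  class(grid) <- c("kinetic_assay", class(grid))
  grid
}
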