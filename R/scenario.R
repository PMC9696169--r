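#' Configuration for the packaged synthetic study scenario
#'
#' Parameterises an end-to-end synthetic experiment that emulates the design
#' of a cytokine-stimulated reconstituted-epidermis study: five groups
#' (CTL, CYT, CYT_IDL, CYT_IDC, CYT_IDL_IDC) with three replicates each, a
#' planted cytokine program shared by all cytokine-containing groups, diffuse
#' treatment programs anti-correlated with a TNF-like external contrast and
#' uncorrelated with a Th2-like one, a disease-signature gene set concordant
#' with the cytokine program, and a kinetic inhibition assay with known
#' inhibition fractions.
#'
#' @param seed Integer seed for all generation.
#' @param out_dir Optional output directory for [run_pipeline()] artifacts.
#' @param n_genes Gene-universe size (default 14000).
#' @param n_cyt_up,n_cyt_down Planted cytokine-increased/-decreased genes
#'   (defaults 350 / 150) at `cyt_shift` log2 units.
#' @param cyt_shift Magnitude of the planted cytokine shifts (default 1
#'   log2 unit).
#' @param treatment_sd SD of the diffuse per-gene treatment effects
#'   (default 0.4 log2 units).
#' @param treatment_tnf_cor Planted correlation between treatment effects
#'   and the TNF-like reference effects (default -0.4).
#' @param external_noise_sd Estimation noise added to the external contrast
#'   tables (default 0.1 log2 units).
#' @param gene_sd_prior Residual-SD prior for the expression simulation.
#' @param n_signature Disease-signature size (concordant members; default
#'   150) plus `n_signature_neutral` non-differential members (default 50).
#' @param n_signature_neutral See above.
#' @param n_resamples Resamples for signature statistics (default 10000).
#' @param ctl_slope,kinetic_inhibition,kinetic_noise_sd Kinetic-assay
#'   generation settings (defaults 0.04 absorbance/min; fractions 0, 0.5,
#'   0.9 for conditions VEH, IDL, IDC; noise SD 0.01).
#' @return A list of class `run_config`.
#' @export
study_config <- function(seed = 1, out_dir = NULL, n_genes = 14000,
                         n_cyt_up = 350, n_cyt_down = 150, cyt_shift = 1,
                         treatment_sd = 0.4, treatment_tnf_cor = -0.4,
                         external_noise_sd = 0.1,
                         gene_sd_prior = list(d0 = 4, s0 = 0.2),
                         n_signature = 150, n_signature_neutral = 50,
                         n_resamples = 10000,
                         ctl_slope = 0.04,
                         kinetic_inhibition = c(VEH = 0, IDL = 0.5, IDC = 0.9),
                         kinetic_noise_sd = 0.01) {
  cfg <- list(
    seed = check_seed(seed), out_dir = out_dir, n_genes = n_genes,
    groups = c("CTL", "CYT", "CYT_IDL", "CYT_IDC", "CYT_IDL_IDC"),
    replicates_per_group = 3,
    n_cyt_up = n_cyt_up, n_cyt_down = n_cyt_down, cyt_shift = cyt_shift,
    treatment_sd = treatment_sd, treatment_tnf_cor = treatment_tnf_cor,
    external_noise_sd = external_noise_sd, gene_sd_prior = gene_sd_prior,
    n_signature = n_signature, n_signature_neutral = n_signature_neutral,
    n_resamples = n_resamples,
    contrasts = list(
      list(name = "CYT vs CTL", a = "CYT", b = "CTL",
           mode = "fdr", cutoff = 0.10),
      list(name = "CYT_IDL vs CYT", a = "CYT_IDL", b = "CYT",
           mode = "raw_p", cutoff = 0.05),
      list(name = "CYT_IDC vs CYT", a = "CYT_IDC", b = "CYT",
           mode = "raw_p", cutoff = 0.05),
      list(name = "CYT_IDL_IDC vs CYT", a = "CYT_IDL_IDC", b = "CYT",
           mode = "raw_p", cutoff = 0.05)
    ),
    fc_up = 1.50, fc_down = 0.67,
    detection_percentile = 20, min_detected_samples = 2, sd_percentile = 5,
    ctl_slope = ctl_slope, kinetic_inhibition = kinetic_inhibition,
    kinetic_noise_sd = kinetic_noise_sd
  )
  class(cfg) <- "run_config"
  cfg
}

#' Generate the synthetic study inputs described by a configuration
#'
#' Draws the planted effect programs, simulates the expression matrix with
#' ground truth, constructs the concordant disease signature, builds the
#' TNF-like and Th2-like external contrast tables (true effects plus
#' estimation noise, with significance flags on the strong true effects),
#' and simulates the kinetic assay. Deterministic given `config$seed`.
#'
#' @param config A `run_config` from [study_config()].
#' @return A list of class `study_scenario` with elements `experiment`
#'   (`sim_experiment`), `signature` (`gene_signature`), `external` (list of
#'   two contrast tibbles `tnf_like`, `th2_like` with columns `gene`,
#'   `log2fc`, `q`), `assay` (`kinetic_assay`), and `truth` (list with the
#'   planted treatment/reference effect vectors and their realised
#'   correlations).
#' @export
build_scenario <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  n <- config$n_genes
  treated_groups <- setdiff(config$groups, "CTL")
  treatment_groups <- setdiff(treated_groups, "CYT")

  # Program draws use an offset seed so they do not share the stream that
  # generates baselines and noise inside simulate_expression().
  set.seed(config$seed + 1000003L)
  genes <- sprintf("G%06d", seq_len(n))

  # cytokine program: planted in every cytokine-containing group
  de_idx <- sample.int(n, config$n_cyt_up + config$n_cyt_down)
  cyt_shift <- setNames(rep(c(config$cyt_shift, -config$cyt_shift),
                            c(config$n_cyt_up, config$n_cyt_down)),
                        genes[de_idx])

  # diffuse reference programs and anti-correlated treatment programs
  rho <- config$treatment_tnf_cor
  s <- config$treatment_sd
  tnf <- rnorm(n, 0, s)
  th2 <- rnorm(n, 0, s)
  treat <- lapply(setNames(treatment_groups, treatment_groups), function(g) {
    rho * tnf + sqrt(1 - rho^2) * rnorm(n, 0, s)
  })

  effects <- dplyr::bind_rows(
    purrr::map_dfr(treated_groups, function(g) {
      tibble::tibble(group = g, gene = names(cyt_shift),
                     shift = unname(cyt_shift))
    }),
    purrr::map_dfr(treatment_groups, function(g) {
      tibble::tibble(group = g, gene = genes, shift = treat[[g]])
    })
  ) |>
    dplyr::group_by(.data$group, .data$gene) |>
    dplyr::summarise(shift = sum(.data$shift), .groups = "drop") |>
    dplyr::filter(.data$shift != 0)

  design <- sim_design(
    group_names = config$groups, n_genes = n,
    replicates_per_group = config$replicates_per_group,
    gene_sd_prior = config$gene_sd_prior,
    effects = effects, seed = config$seed
  )
  experiment <- simulate_expression(design)

  signature <- simulate_signature(
    experiment, group_a = "CYT", group_b = "CTL",
    n_concordant = config$n_signature, n_discordant = 0,
    n_neutral = config$n_signature_neutral,
    name = "AD_signature", seed = config$seed + 2000003L
  )

  set.seed(config$seed + 3000003L)
  external_table <- function(true_fc) {
    est <- true_fc + rnorm(n, 0, config$external_noise_sd)
    # synthetic significance flags: strong true effects are the "FDR < 0.10"
    # genes of the external study
    q <- ifelse(abs(true_fc) > log2(1.5), 0.01, 0.5)
    tibble::tibble(gene = genes, log2fc = est, fc = 2^est, q = q)
  }
  external <- list(tnf_like = external_table(tnf),
                   th2_like = external_table(th2))

  assay <- simulate_kinetic_assay(
    ctl_slope = config$ctl_slope, inhibition = config$kinetic_inhibition,
    noise_sd = config$kinetic_noise_sd, seed = config$seed + 4000003L
  )

  structure(
    list(experiment = experiment, signature = signature, external = external,
         assay = assay,
         truth = list(
           cyt_shift = cyt_shift, tnf = setNames(tnf, genes),
           th2 = setNames(th2, genes), treatment = treat,
           realised_tnf_cor = vapply(treat, function(v) stats::cor(v, tnf),
                                     numeric(1)),
           realised_th2_cor = vapply(treat, function(v) stats::cor(v, th2),
                                     numeric(1))
         )),
    class = "study_scenario"
  )
}
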