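#' Run the full analysis pipeline on the synthetic study scenario
#'
#' Executes the stages in dependency order: scenario generation (or use of a
#' pre-built scenario), per-comparison gene filtering, the four moderated
#' contrasts with BH adjustment and DEG calling at the configured
#' thresholds, signature enrichment reports for the increased and decreased
#' signature arms, fold-change cross-comparisons of each treatment contrast
#' against the TNF-like and Th2-like external contrasts, sample-structure
#' summaries, and the kinetic-assay statistics. When `config$out_dir` is
#' set, every stage output is written as plain text and hashed into a run
#' manifest.
#'
#' @param config A `run_config` from [study_config()].
#' @param scenario Optional pre-built `study_scenario` (otherwise generated
#'   from `config`).
#' @param quiet Suppress stage messages (default `TRUE`).
#' @return A list of class `pipeline_run` with elements `config`,
#'   `scenario`, `filtered` (per-contrast gene universes), `contrasts`
#'   (named list of moderated, adjusted `contrast_result`s), `degs` (named
#'   list of `deg_call`s), `deg_counts` (tibble), `signature_reports`
#'   (tibble: one row per signature arm), `crosscompare` (tibble: one row
#'   per treatment x reference pair), `structure` (list: `pca`,
#'   `clustering`, `group_profiles`), `assay` (inhibition summary tibble),
#'   and `manifest` (tibble of written files and their MD5 hashes, or
#'   `NULL`).
#' @export
run_pipeline <- function(config, scenario = NULL, quiet = TRUE) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  say <- function(...) if (!quiet) message(...)

  say("stage: simulate")
  scenario <- scenario %||% build_scenario(config)
  expr <- scenario$experiment$expr
  samples <- scenario$experiment$samples

  say("stage: preprocess + contrasts")
  filtered <- list()
  contrasts <- list()
  degs <- list()
  for (ct in config$contrasts) {
    comparison <- samples$sample[samples$group %in% c(ct$a, ct$b)]
    sub <- filter_detection(expr, comparison,
                            detection_percentile = config$detection_percentile,
                            min_detected_samples = config$min_detected_samples)
    sub <- filter_variance(sub, comparison,
                           sd_percentile = config$sd_percentile)
    say("  ", ct$name, ": ", nrow(sub), " genes after filtering")
    fit <- fit_contrast(sub, samples, ct$a, ct$b, name = ct$name) |>
      moderate() |>
      adjust_bh()
    filtered[[ct$name]] <- sub$gene
    contrasts[[ct$name]] <- fit
    degs[[ct$name]] <- call_degs(fit, significance_mode = ct$mode,
                                 cutoff = ct$cutoff,
                                 fc_up = config$fc_up, fc_down = config$fc_down)
  }
  deg_counts <- purrr::imap_dfr(degs, function(d, nm) {
    tibble::tibble(contrast = nm,
                   n_increased = sum(d$direction == "increased"),
                   n_decreased = sum(d$direction == "decreased"))
  })

  say("stage: signature enrichment")
  cyt_name <- config$contrasts[[1]]$name
  cyt_fit <- contrasts[[cyt_name]]
  cyt_degs <- degs[[cyt_name]]
  sig <- scenario$signature
  arms <- list(
    increased = sig[!is.na(sig$direction) & sig$direction == "increased", ],
    decreased = sig[!is.na(sig$direction) & sig$direction == "decreased", ]
  )
  signature_reports <- purrr::imap_dfr(arms, function(arm, dir) {
    if (nrow(arm) == 0) return(NULL)
    rep <- signature_report(
      cyt_fit, cyt_degs, arm$gene,
      alternative = if (dir == "increased") "greater" else "less",
      n_resamples = config$n_resamples, seed = config$seed
    )
    rep$signature <- paste0(sig$signature[1], "_", dir)
    rep
  })

  say("stage: cross-comparison")
  treatment_names <- vapply(config$contrasts[-1], `[[`, character(1), "name")
  crosscompare <- purrr::map_dfr(treatment_names, function(tn) {
    purrr::imap_dfr(scenario$external, function(ref, ref_name) {
      paired <- align_contrasts(ref, contrasts[[tn]],
                                label_x = ref_name, label_y = tn)
      cor_res <- spearman_fc(paired)
      quad <- quadrant_proportions(paired)
      ell <- mahalanobis_ellipse(paired, coverage = 0.90)
      disc <- discordant_genes(paired, reference_direction = "up",
                               reference_q_max = 0.10,
                               response_fc_threshold = config$fc_down)
      tibble::tibble(treatment = tn, reference = ref_name,
                     n_shared = nrow(paired), rho = cor_res$rho,
                     rho_p = cor_res$p,
                     up_up = quad$up_up, up_down = quad$up_down,
                     down_down = quad$down_down, down_up = quad$down_up,
                     n_in_ellipse = sum(ell$in_ellipse),
                     n_discordant = nrow(disc))
    })
  })

  say("stage: sample structure")
  pca <- pca_scores(expr, n_components = 4)
  clustering <- hierarchical_cluster(expr)
  structure_out <- list(pca = pca, clustering = clustering,
                        group_profiles = group_pc_profiles(pca, samples))

  say("stage: assay statistics")
  assay_out <- inhibition_summary(scenario$assay, control = "CTL")

  run <- list(config = config, scenario = scenario, filtered = filtered,
              contrasts = contrasts, degs = degs, deg_counts = deg_counts,
              signature_reports = signature_reports,
              crosscompare = crosscompare, structure = structure_out,
              assay = assay_out, manifest = NULL)
  class(run) <- "pipeline_run"

  if (!is.null(config$out_dir)) {
    run$manifest <- write_run(run, config$out_dir)
  }
  run
}

# Persist all stage outputs as plain text and hash them into a manifest.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add <- function(p) paths <<- c(paths, p)

  add(write_expression(run$scenario$experiment$expr,
                       file.path(out_dir, "expression.tsv")))
  add(write_sample_map(run$scenario$experiment$samples,
                       file.path(out_dir, "samples.tsv")))
  add(write_gmt(run$scenario$signature, file.path(out_dir, "signatures.gmt")))
  for (nm in names(run$contrasts)) {
    p <- file.path(out_dir, paste0("contrast_", gsub("\\W+", "_", nm), ".tsv"))
    add(write_contrast(run$contrasts[[nm]], p))
  }
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    add(p)
  }
  tsv(run$deg_counts, "deg_counts.tsv")
  tsv(run$signature_reports, "signature_reports.tsv")
  tsv(run$crosscompare, "crosscompare.tsv")
  tsv(run$structure$pca$scores, "pca_scores.tsv")
  tsv(tibble::tibble(component = paste0("PC", seq_along(run$structure$pca$variance_explained)),
                     variance_explained = run$structure$pca$variance_explained),
      "pca_variance.tsv")
  tsv(run$structure$group_profiles, "group_pc_profiles.tsv")
  tsv(run$assay, "assay_inhibition.tsv")
  if (requireNamespace("ape", quietly = TRUE)) {
    p <- file.path(out_dir, "sample_dendrogram.nwk")
    cluster_newick(run$structure$clustering, p)
    add(p)
  }
  summary_json <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(
    list(seed = run$config$seed, n_genes = run$config$n_genes,
         deg_counts = run$deg_counts, crosscompare = run$crosscompare),
    summary_json, auto_unbox = TRUE, digits = NA
  )
  add(summary_json)

  tibble::tibble(file = basename(paths),
                 md5 = unname(tools::md5sum(paths)))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> seed ", x$config$seed, ", ",
      x$config$n_genes, " genes\n", sep = "")
  print(x$deg_counts)
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Reads scalar overrides for [study_config()] fields from YAML, so runs
#' can be parameterised from plain-text files.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(study_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$kinetic_inhibition)) {
    raw$kinetic_inhibition <- unlist(raw$kinetic_inhibition)
  }
  do.call(study_config, raw)
}
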