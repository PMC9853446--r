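# End-to-end orchestration of the signature workflow on synthetic data with
# known ground truth: simulate -> derive (DE + filtration cascade) ->
# score -> compare (high-vs-low DE and enrichment) -> survive.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full signature-derivation workflow
#'
#' Generates every synthetic input from one master seed, derives candidate
#' markers by the pairwise/union DEG criterion, refines them through the
#' specificity-filtration cascade, scores bulk mixtures with the recovered
#' signature, stratifies, runs high-versus-low differential expression and a
#' competitive enrichment test of the signature, and fits survival models on
#' a cohort whose hazard depends on the score group. All artifacts (ledger,
#' signature GMT, scores, DEG tables, survival outputs, ground truth and a
#' provenance record) are written under `out_dir`; reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list with the in-memory results (`signature`, `ledger`,
#'   `truth`, `scores`, `deg`, `enrichment`, `logrank`, `cox`, `km`,
#'   `paths`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  check(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  check(!missing(out_dir) && is.character(out_dir), "out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    scfg <- synth_config(
      n_genes = config$n_genes, cell_types = config$cell_types,
      n_replicates = config$n_replicates, n_markers = config$n_markers,
      n_leaky = config$n_leaky, n_stromal = config$n_stromal,
      marker_fold = config$marker_fold, dispersion = config$dispersion,
      dropout_rate = config$dropout_rate,
      n_cells_per_type = config$n_cells_per_type, seed = config$seed)
    immune <- generate_sorted_immune(scfg)
    truth <- immune$truth
    lines <- generate_cell_lines(scfg, truth$planted_leaky_genes,
                                 n_lines = config$n_lines)
    comps <- generate_compartments(scfg, truth$planted_stromal_genes,
                                   n_patients = config$n_patients)
    sc <- generate_single_cell(scfg)
    list(scfg = scfg, immune = immune, truth = truth, lines = lines,
         comps = comps, sc = sc)
  })

  # -- derive --------------------------------------------------------------
  derived <- run_stage("derive", {
    keep <- filter_low_expression(sim$immune$counts, config$min_cpm,
                                  config$min_samples)
    norm <- to_log_cpm(sim$immune$counts[keep, , drop = FALSE], config$pseudo)
    pairwise <- pairwise_nk_degs(norm, sim$immune$annotation$cell_type,
                                 target = "NK", lfc_cut = config$lfc_cut,
                                 alpha = config$alpha)
    candidates <- merge_union_degs(list(immune = pairwise))
    cascade <- apply_cascade(
      candidates,
      immune_datasets = list(list(norm = norm,
                                  labels = sim$immune$annotation$cell_type)),
      line_panels = list(to_log_cpm(sim$lines, config$pseudo)),
      compartments = list(expr = cpm(sim$comps$counts),
                          labels = sim$comps$annotation$compartment,
                          patients = sim$comps$annotation$patient),
      sc_data = list(counts = sim$sc$counts, labels = sim$sc$labels),
      config = cascade_config(
        target = "NK", median = config$filter_median,
        tumour = config$filter_tumour, stromal = config$filter_stromal,
        sc = config$filter_sc,
        stromal_significance = config$stromal_significance,
        ratio_cut = config$ratio_cut, frac_cut = config$frac_cut,
        k = config$k))
    list(candidates = candidates, cascade = cascade)
  })
  signature <- derived$cascade$signature

  # -- score ---------------------------------------------------------------
  scored <- run_stage("score", {
    check(length(signature) > 0L, "empty signature; nothing to score")
    ref <- mixture_reference(sim$immune)
    fractions <- with_seed(config$seed + 606L,
                           stats::runif(config$n_mixtures, 0,
                                        config$mixture_fraction_max))
    mix <- generate_bulk_mixtures(ref$nk, ref$background, fractions, sim$scfg)
    scores <- score_cohort(mix$counts, signature)
    scores$group <- stratify(scores, method = "decile", q = config$q)
    list(mix = mix, scores = scores)
  })

  # -- compare -------------------------------------------------------------
  compared <- run_stage("compare", {
    keep <- filter_low_expression(scored$mix$counts, config$min_cpm,
                                  min_samples = 2L)
    norm <- to_log_cpm(scored$mix$counts[keep, , drop = FALSE], config$pseudo)
    deg <- de_high_vs_low(norm, scored$scores$group,
                          lfc_cut = config$lfc_cut, alpha = config$alpha)
    enr <- competitive_set_test(stats::setNames(deg$t, deg$gene), signature)
    list(deg = deg, enrichment = enr)
  })

  # -- survive -------------------------------------------------------------
  survived <- run_stage("survive", {
    med_groups <- stratify(scored$scores, method = "median")
    clinical <- generate_survival_cohort(med_groups, config$survival_log_hr,
                                         censoring_rate = config$censoring_rate,
                                         seed = config$seed + 707L)
    km <- km_estimate(clinical)
    lr <- logrank_test(clinical)
    cox <- cox_fit(clinical)
    list(clinical = clinical, km = km, logrank = lr, cox = cox)
  })

  # -- artifacts -----------------------------------------------------------
  paths <- run_stage("write", {
    p <- c(
      ledger = pth("filter_ledger.tsv"),
      candidates = pth("candidates.txt"),
      scores = pth("scores.tsv"),
      deg = pth("deg_high_vs_low.tsv"),
      enrichment = pth("enrichment.json"),
      clinical = pth("clinical.tsv"),
      km = pth("km_curves.tsv"),
      logrank = pth("logrank.json"),
      cox = pth("cox_summary.tsv"),
      truth = pth("ground_truth.json"),
      config = pth("config.json"),
      provenance = pth("provenance.json")
    )
    write_table_file(derived$cascade$ledger, p[["ledger"]])
    writeLines(derived$candidates, p[["candidates"]])
    if (length(signature) > 0L) {
      p <- c(p, signature = pth("signature.gmt"))
      write_gmt(list(nk_signature = signature), p[["signature"]])
    }
    write_table_file(scored$scores, p[["scores"]])
    write_table_file(as.data.frame(compared$deg), p[["deg"]])
    write_json_file(unclass(compared$enrichment), p[["enrichment"]])
    write_table_file(survived$clinical, p[["clinical"]])
    write_table_file(as.data.frame(survived$km), p[["km"]])
    write_json_file(unclass(survived$logrank), p[["logrank"]])
    write_table_file(survived$cox$coefficients, p[["cox"]])
    write_json_file(list(
      planted_nk_markers = sim$truth$planted_nk_markers,
      planted_leaky_genes = sim$truth$planted_leaky_genes,
      planted_stromal_genes = sim$truth$planted_stromal_genes,
      nk_fraction_per_sample = as.list(scored$mix$truth$nk_fraction_per_sample),
      true_log_hazard_ratio = config$survival_log_hr
    ), p[["truth"]])
    write_json_file(unclass(config), p[["config"]])
    write_json_file(list(
      package = "nksig",
      package_version = as.character(utils::packageVersion("nksig")),
      r_version = R.version.string,
      seed = config$seed,
      config_md5 = unname(tools::md5sum(p[["config"]]))
    ), p[["provenance"]])
    p
  })

  invisible(list(signature = signature, ledger = derived$cascade$ledger,
                 candidates = derived$candidates, truth = sim$truth,
                 scores = scored$scores, mixture_truth = scored$mix$truth,
                 deg = compared$deg, enrichment = compared$enrichment,
                 clinical = survived$clinical, km = survived$km,
                 logrank = survived$logrank, cox = survived$cox,
                 paths = paths))
}
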