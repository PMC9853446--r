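# Synthetic-data generators with known ground truth: sorted immune
# reference panels, tumour cell-line panels, patient compartment quadruplets,
# labelled single-cell counts with dropout, bulk mixtures with a latent NK
# fraction, and censored survival cohorts with a planted hazard ratio.
#
# Counts follow a negative-binomial law with log-normal per-gene baselines
# and log-normal library sizes, matching the overdispersion and depth
# variation the DE engine must tolerate. Setting `dispersion = 0` switches
# every generator to noise-free expected values (deterministic mode), which
# the oracle tests rely on. All randomness flows through one RNG stream per
# generator call, derived from `seed` plus a fixed per-generator offset, so
# identical configurations reproduce bit-identical outputs and paired
# generator outputs share one gene universe and one planted-marker truth.

#' Synthetic-data configuration
#'
#' @param n_genes number of genes (default 2000).
#' @param cell_types immune cell-type labels; must include `"NK"`.
#' @param n_replicates sorted-sample replicates per cell type (>= 2).
#' @param n_markers planted NK marker genes (`< n_genes`).
#' @param n_leaky planted markers also expressed by tumour cell lines.
#' @param n_stromal planted markers also expressed by a stromal compartment.
#' @param marker_fold linear fold-change of markers in NK samples (> 1).
#' @param leaky_fold linear fold of leaky genes in tumour lines.
#' @param stromal_fold linear fold of stromal genes in the fibroblast
#'   compartment relative to leukocytes.
#' @param baseline_mu,baseline_sigma log-normal parameters of per-gene
#'   baseline means.
#' @param dispersion negative-binomial dispersion (0 = deterministic
#'   expected-value mode).
#' @param dropout_rate independent Bernoulli zeroing probability for
#'   single-cell mode, in `[0, 1]`.
#' @param n_cells_per_type cells per type in single-cell mode.
#' @param library_size,library_sigma bulk library-size log-normal parameters
#'   (median and sdlog).
#' @param sc_library_size,sc_library_sigma single-cell library-size
#'   parameters.
#' @param seed integer seed for all generators using this configuration.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000L,
                         cell_types = c("NK", "T", "B", "Monocyte",
                                        "Neutrophil", "DC", "Myeloid"),
                         n_replicates = 4L,
                         n_markers = 30L, n_leaky = 5L, n_stromal = 5L,
                         marker_fold = 8, leaky_fold = 10, stromal_fold = 5,
                         baseline_mu = log(50), baseline_sigma = 1.2,
                         dispersion = 0.1, dropout_rate = 0.3,
                         n_cells_per_type = 60L,
                         library_size = 1e7, library_sigma = 0.2,
                         sc_library_size = 1e4, sc_library_sigma = 0.3,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), cell_types = as.character(cell_types),
              n_replicates = as.integer(n_replicates),
              n_markers = as.integer(n_markers), n_leaky = as.integer(n_leaky),
              n_stromal = as.integer(n_stromal),
              marker_fold = marker_fold, leaky_fold = leaky_fold,
              stromal_fold = stromal_fold,
              baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
              dispersion = dispersion, dropout_rate = dropout_rate,
              n_cells_per_type = as.integer(n_cells_per_type),
              library_size = library_size, library_sigma = library_sigma,
              sc_library_size = sc_library_size, sc_library_sigma = sc_library_sigma,
              seed = as.integer(seed))
  check(cfg$n_genes >= 10L, "n_genes must be at least 10")
  check("NK" %in% cfg$cell_types, "cell_types must include 'NK'")
  check(length(cfg$cell_types) >= 2L, "need at least 2 cell types")
  check(cfg$n_replicates >= 2L,
        "each cell type needs at least 2 replicates (downstream DE needs residual df)")
  check(cfg$n_markers >= 0L && cfg$n_markers < cfg$n_genes,
        "n_markers must be non-negative and smaller than n_genes")
  check(cfg$n_leaky + cfg$n_stromal <= cfg$n_markers,
        "leaky + stromal genes must fit within the planted markers")
  check(cfg$marker_fold > 1, "marker_fold must exceed 1")
  check(cfg$dispersion >= 0, "dispersion must be non-negative")
  check(cfg$dropout_rate >= 0 && cfg$dropout_rate <= 1,
        "dropout_rate must lie in [0, 1]")
  class(cfg) <- "synth_config"
  cfg
}

# Deterministic per-config gene universe, baselines and planted-gene truth.
# Uses its own sub-stream so every generator sharing the config agrees.
synth_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    baselines <- stats::rlnorm(config$n_genes, config$baseline_mu,
                               config$baseline_sigma)
    names(baselines) <- genes
    markers <- sort(sample(genes, config$n_markers))
    leaky <- if (config$n_leaky > 0L) markers[seq_len(config$n_leaky)] else character(0)
    stromal <- if (config$n_stromal > 0L) {
      markers[seq.int(config$n_leaky + 1L, config$n_leaky + config$n_stromal)]
    } else {
      character(0)
    }
    list(genes = genes, baselines = baselines,
         planted_nk_markers = markers,
         planted_leaky_genes = leaky,
         planted_stromal_genes = stromal)
  })
}

# Draw counts around a matrix of expected values; dispersion 0 returns the
# expectations themselves (deterministic mode).
nb_draw <- function(mu, dispersion) {
  if (dispersion == 0) return(mu)
  out <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                               size = 1 / dispersion),
                nrow = nrow(mu), dimnames = dimnames(mu))
  out
}

# Scale per-sample expected expression to target library sizes.
scale_to_libraries <- function(means, libs) {
  sweep(means, 2L, libs / colSums(means), "*")
}

#' Generate a sorted-immune reference panel
#'
#' FACS-sorted replicate samples per immune cell type; planted NK markers
#' have expected expression `marker_fold` times baseline in NK samples only.
#'
#' @param config a [synth_config()].
#' @return list with `counts` (genes x samples), `annotation` (data frame
#'   `sample`, `cell_type`) and `truth` (planted gene sets and baselines).
#' @export
generate_sorted_immune <- function(config) {
  truth <- synth_truth(config)
  types <- config$cell_types
  n_samp <- length(types) * config$n_replicates
  labels <- rep(types, each = config$n_replicates)
  samples <- paste(labels, rep(seq_len(config$n_replicates), length(types)),
                   sep = "_")
  means <- matrix(truth$baselines, nrow = config$n_genes, ncol = n_samp,
                  dimnames = list(truth$genes, samples))
  means[truth$planted_nk_markers, labels == "NK"] <-
    means[truth$planted_nk_markers, labels == "NK"] * config$marker_fold
  with_seed(config$seed + 101L, {
    libs <- stats::rlnorm(n_samp, log(config$library_size), config$library_sigma)
    counts <- nb_draw(scale_to_libraries(means, libs), config$dispersion)
  })
  list(counts = counts,
       annotation = data.frame(sample = samples, cell_type = labels,
                               stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a tumour cell-line panel
#'
#' Colorectal-cancer-like cell lines sharing the configuration's gene
#' universe. Leaky genes are expressed `leaky_fold` times baseline; all other
#' planted NK markers are near zero (lines carry no NK programme); background
#' genes stay at baseline.
#'
#' @param config a [synth_config()].
#' @param leaky_genes genes expressed by the lines (must belong to the gene
#'   universe); typically `truth$planted_leaky_genes`.
#' @param n_lines number of cell lines (default 20).
#' @return genes x lines count matrix.
#' @export
generate_cell_lines <- function(config, leaky_genes = character(0), n_lines = 20L) {
  truth <- synth_truth(config)
  check(all(leaky_genes %in% truth$genes), "unknown gene id in leaky_genes")
  lines <- sprintf("LINE%02d", seq_len(n_lines))
  means <- matrix(truth$baselines, nrow = config$n_genes, ncol = n_lines,
                  dimnames = list(truth$genes, lines))
  silent <- setdiff(truth$planted_nk_markers, leaky_genes)
  means[silent, ] <- means[silent, ] * 0.02
  means[leaky_genes, ] <- means[leaky_genes, ] * config$leaky_fold
  with_seed(config$seed + 202L, {
    libs <- stats::rlnorm(n_lines, log(config$library_size), config$library_sigma)
    nb_draw(scale_to_libraries(means, libs), config$dispersion)
  })
}

#' Generate patient compartment quadruplets
#'
#' Per patient: leukocyte (CD45), endothelial (CD31), fibroblast (FAP) and
#' epithelial (EpCAM) sorted fractions. Stromal genes are expressed
#' `stromal_fold` times baseline in the FAP compartment; planted NK markers
#' are confined to the leukocyte fraction; background genes are flat across
#' compartments.
#'
#' @param config a [synth_config()].
#' @param stromal_genes genes planted as stromal contaminants (in the gene
#'   universe); typically `truth$planted_stromal_genes`.
#' @param n_patients number of patients (>= 3, default 6).
#' @return list with `counts`, `annotation` (`sample`, `compartment`,
#'   `patient`) and `truth`.
#' @export
generate_compartments <- function(config, stromal_genes = character(0),
                                  n_patients = 6L) {
  truth <- synth_truth(config)
  check(n_patients >= 3L, "need at least 3 patients")
  check(all(stromal_genes %in% truth$genes), "unknown gene id in stromal_genes")
  comps <- c("CD45", "CD31", "FAP", "EpCAM")
  patients <- sprintf("P%02d", seq_len(n_patients))
  labels <- rep(comps, times = n_patients)
  pats <- rep(patients, each = length(comps))
  samples <- paste(pats, labels, sep = "_")
  means <- matrix(truth$baselines, nrow = config$n_genes, ncol = length(samples),
                  dimnames = list(truth$genes, samples))
  non_leuko <- labels != "CD45"
  means[truth$planted_nk_markers, non_leuko] <-
    means[truth$planted_nk_markers, non_leuko] * 0.05
  if (length(stromal_genes) > 0L) {
    means[stromal_genes, labels == "FAP"] <-
      truth$baselines[stromal_genes] * config$stromal_fold
  }
  with_seed(config$seed + 303L, {
    libs <- stats::rlnorm(length(samples), log(config$library_size),
                          config$library_sigma)
    counts <- nb_draw(scale_to_libraries(means, libs), config$dispersion)
  })
  list(counts = counts,
       annotation = data.frame(sample = samples, compartment = labels,
                               patient = pats, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a labelled single-cell count matrix
#'
#' Per-cell-type expression structure mirrors [generate_sorted_immune()]
#' (planted markers up `marker_fold`-fold in NK cells), with shallow
#' log-normal library sizes and independent Bernoulli dropout zeroing each
#' entry with probability `dropout_rate`.
#'
#' @param config a [synth_config()].
#' @return list with `counts` (sparse `dgCMatrix`, genes x cells),
#'   `labels` (cell type per cell) and `truth`.
#' @export
generate_single_cell <- function(config) {
  truth <- synth_truth(config)
  types <- config$cell_types
  n_cells <- length(types) * config$n_cells_per_type
  labels <- rep(types, each = config$n_cells_per_type)
  cells <- paste0("C", seq_len(n_cells), "_", labels)
  means <- matrix(truth$baselines, nrow = config$n_genes, ncol = n_cells,
                  dimnames = list(truth$genes, cells))
  means[truth$planted_nk_markers, labels == "NK"] <-
    means[truth$planted_nk_markers, labels == "NK"] * config$marker_fold
  with_seed(config$seed + 404L, {
    libs <- stats::rlnorm(n_cells, log(config$sc_library_size),
                          config$sc_library_sigma)
    counts <- nb_draw(scale_to_libraries(means, libs), config$dispersion)
    if (config$dropout_rate > 0) {
      keep <- matrix(stats::rbinom(length(counts), 1L,
                                   1 - config$dropout_rate),
                     nrow = nrow(counts))
      counts <- counts * keep
    }
  })
  list(counts = Matrix::Matrix(counts, sparse = TRUE),
       labels = labels, truth = truth)
}

#' Generate bulk tumour mixtures with a latent NK fraction
#'
#' Each sample's expected expression is
#' `fraction * NK profile + (1 - fraction) * background profile`, rescaled to
#' a log-normal library size, with negative-binomial noise
#' (`dispersion = 0` gives the exact expectations).
#'
#' @param nk_profile,background_profile named linear-scale expression
#'   profiles over a common gene universe (e.g. mean CPM of NK and of pooled
#'   non-NK sorted samples).
#' @param fractions vector of NK fractions in `[0, 1]`, one per sample.
#' @param config a [synth_config()] supplying dispersion, library-size law
#'   and seed.
#' @return list with `counts` (genes x samples) and `truth`
#'   (`nk_fraction_per_sample`).
#' @export
generate_bulk_mixtures <- function(nk_profile, background_profile, fractions,
                                   config) {
  check(is.numeric(nk_profile) && is.numeric(background_profile),
        "profiles must be numeric vectors")
  check(identical(names(nk_profile), names(background_profile)) &&
          !is.null(names(nk_profile)),
        "profiles must share one named gene universe")
  check(all(fractions >= 0 & fractions <= 1), "fractions must lie in [0, 1]")
  n <- length(fractions)
  samples <- sprintf("MIX%03d", seq_len(n))
  means <- vapply(fractions, function(f) f * nk_profile + (1 - f) * background_profile,
                  numeric(length(nk_profile)))
  dimnames(means) <- list(names(nk_profile), samples)
  with_seed(config$seed + 505L, {
    libs <- stats::rlnorm(n, log(config$library_size), config$library_sigma)
    counts <- nb_draw(scale_to_libraries(means, libs), config$dispersion)
  })
  list(counts = counts,
       truth = list(nk_fraction_per_sample = stats::setNames(fractions, samples)))
}

#' Build NK and background mixture profiles from a sorted-immune panel
#'
#' Mean CPM of the NK samples and of all non-NK samples, for use with
#' [generate_bulk_mixtures()].
#'
#' @param immune output of [generate_sorted_immune()].
#' @param target target cell type (default `"NK"`).
#' @return list with `nk` and `background` named profiles.
#' @export
mixture_reference <- function(immune, target = "NK") {
  norm <- cpm(immune$counts)
  is_t <- immune$annotation$cell_type == target
  list(nk = rowMeans(norm[, is_t, drop = FALSE]),
       background = rowMeans(norm[, !is_t, drop = FALSE]))
}

#' Generate a censored survival cohort with a planted hazard ratio
#'
#' Exponential event times with the baseline hazard multiplied by
#' `exp(true_log_hr)` for the `high` group; independent exponential censoring
#' whose rate targets the requested censoring fraction (approximately, since
#' the two groups have different event hazards); independent clinical
#' covariates (age in years, ordinal stage 1-3, binary MMR status) unless a
#' confounding coefficient is supplied.
#'
#' @param groups character/factor of `high`/`low` per subject, or a numeric
#'   score vector (median-split via [stratify()]).
#' @param true_log_hr planted log hazard ratio of the high group.
#' @param censoring_rate target censoring fraction in `[0, 1)`; 0 means no
#'   censoring.
#' @param seed integer seed.
#' @param base_hazard baseline event rate per unit time (default 0.01).
#' @param confound_beta optional log-hazard effect of MMR status shared with
#'   group assignment; default 0 (covariates independent of group).
#' @return data frame (`sample`, `time`, `event`, `group`, `age`, `stage`,
#'   `mmr`).
#' @export
generate_survival_cohort <- function(groups, true_log_hr, censoring_rate = 0.2,
                                     seed = 1L, base_hazard = 0.01,
                                     confound_beta = 0) {
  check(censoring_rate >= 0 && censoring_rate < 1,
        "censoring_rate must lie in [0, 1)")
  if (is.numeric(groups)) {
    groups <- stratify(groups, method = "median")
  }
  groups <- as.character(groups)
  check(all(groups %in% c("high", "low")), "groups must be 'high'/'low'")
  n <- length(groups)
  with_seed(seed, {
    age <- round(stats::rnorm(n, 65, 10))
    stage <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    mmr <- stats::rbinom(n, 1L, 0.2)
    loghaz <- log(base_hazard) + true_log_hr * (groups == "high") +
      confound_beta * mmr
    t_event <- stats::rexp(n, rate = exp(loghaz))
    if (censoring_rate > 0) {
      cens_rate <- base_hazard * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n, rate = cens_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(sample = sprintf("S%04d", seq_len(n)),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               group = groups, age = age, stage = stage, mmr = mmr,
               stringsAsFactors = FALSE)
  })
}
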