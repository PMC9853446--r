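# Specificity-filtration cascade: immune median-dominance filter, tumour
# cell-line filter, stromal/fibroblast ratio filter, single-cell specificity
# classification, and the orchestrated cascade with a per-gene ledger.

row_median_by <- function(mat, labels) {
  lev <- unique(labels)
  out <- vapply(lev, function(l) {
    apply(mat[, labels == l, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), lev))
}

#' Immune median-dominance filter
#'
#' A gene passes if its median expression in the target cell type is strictly
#' greater than its median in *every* other immune cell type of the dataset.
#' Strict comparison: ties fail (conservative specificity). Apply per dataset;
#' combine datasets by intersecting the passing sets.
#'
#' @param norm genes x samples matrix (log2-CPM or any monotone scale).
#' @param cell_labels cell-type label per sample.
#' @param target target cell type (default `"NK"`).
#' @param genes optional subset of genes to evaluate (default: all rows).
#'   Genes absent from the matrix fail (no evidence of specificity).
#' @return character vector of passing genes; attribute `"evidence"` holds a
#'   data frame with per-gene `median_target`, `median_other_max` and `pass`.
#' @export
median_specificity_filter <- function(norm, cell_labels, target = "NK",
                                      genes = NULL) {
  check_matrix(norm, "normalized matrix")
  cell_labels <- as.character(cell_labels)
  check(length(cell_labels) == ncol(norm), "cell_labels must match samples")
  check(target %in% cell_labels, sprintf("target label '%s' not found", target))
  check(length(setdiff(cell_labels, target)) >= 1L, "need at least one other cell type")
  genes <- genes %||% rownames(norm)
  present <- genes[genes %in% rownames(norm)]
  if (length(present) == 0L) {
    evidence <- data.frame(gene = genes, median_target = NA_real_,
                           median_other_max = NA_real_, pass = FALSE,
                           stringsAsFactors = FALSE)
    return(structure(character(0), evidence = evidence))
  }
  med <- row_median_by(norm[present, , drop = FALSE], cell_labels)
  m_target <- med[, target]
  m_other <- med[, setdiff(colnames(med), target), drop = FALSE]
  other_max <- apply(m_other, 1L, max)
  pass_present <- m_target > other_max
  evidence <- data.frame(
    gene = genes,
    median_target = m_target[match(genes, present)],
    median_other_max = other_max[match(genes, present)],
    pass = genes %in% present[pass_present],
    stringsAsFactors = FALSE
  )
  structure(evidence$gene[evidence$pass], evidence = evidence)
}

#' Tumour cell-line filter
#'
#' A gene fails if its median expression across tumour cell lines is strictly
#' greater than its median across reference NK samples, i.e. the line panel
#' expresses it at least as strongly as NK cells do. With several panels the
#' caller (or [apply_cascade()]) takes the union of failing genes.
#'
#' @param nk_norm genes x NK-samples matrix.
#' @param line_norm genes x cell-line matrix on a comparable scale.
#' @param genes optional subset to evaluate; genes outside the shared gene
#'   universe cannot show contamination and therefore pass.
#' @return character vector of failing genes; attribute `"evidence"` with
#'   per-gene `nk_median`, `line_median`, `fail`.
#' @export
tumour_line_filter <- function(nk_norm, line_norm, genes = NULL) {
  check_matrix(nk_norm, "NK reference matrix")
  check_matrix(line_norm, "cell-line matrix")
  shared <- intersect(rownames(nk_norm), rownames(line_norm))
  check(length(shared) > 0L, "empty intersection of gene universes")
  genes <- genes %||% shared
  present <- genes[genes %in% shared]
  nk_med <- apply(nk_norm[present, , drop = FALSE], 1L, stats::median)
  line_med <- apply(line_norm[present, , drop = FALSE], 1L, stats::median)
  fail_present <- line_med > nk_med
  evidence <- data.frame(
    gene = genes,
    nk_median = nk_med[match(genes, present)],
    line_median = line_med[match(genes, present)],
    fail = genes %in% present[fail_present],
    stringsAsFactors = FALSE
  )
  structure(evidence$gene[evidence$fail], evidence = evidence)
}

#' Stromal-compartment filter
#'
#' Compares, within each patient, linear expression in each non-leukocyte
#' compartment (e.g. CD31+ endothelium, FAP+ fibroblasts, EpCAM+ epithelium)
#' against the matched leukocyte (CD45+) sample. A gene fails if, in at least
#' one non-leukocyte compartment, the mean patient-wise ratio exceeds 1 and
#' (when `significance = TRUE`) a one-sided paired t-test of log-ratios > 0 is
#' significant at `alpha`.
#'
#' @param expr genes x samples matrix on a linear scale (counts or CPM).
#' @param compartment_labels compartment per sample (must include
#'   `leukocyte_label`).
#' @param patient_ids patient per sample; each patient needs one leukocyte
#'   sample (replicates are averaged) and at least one other compartment.
#' @param leukocyte_label the reference compartment (default `"CD45"`).
#' @param genes optional subset; absent genes pass (no evidence).
#' @param significance require the paired test as well as mean ratio > 1.
#' @param alpha one-sided test level (default 0.05).
#' @param eps pseudo-expression added to both numerator and denominator to
#'   keep ratios finite at zero expression.
#' @return character vector of failing genes; attribute `"evidence"` with
#'   `max_ratio` (largest compartment mean ratio), `which_compartment`,
#'   `p` (paired test in that compartment) and `fail`.
#' @export
stromal_filter <- function(expr, compartment_labels, patient_ids,
                           leukocyte_label = "CD45", genes = NULL,
                           significance = TRUE, alpha = 0.05, eps = 0.5) {
  check_matrix(expr, "compartment matrix")
  compartment_labels <- as.character(compartment_labels)
  patient_ids <- as.character(patient_ids)
  check(length(compartment_labels) == ncol(expr) && length(patient_ids) == ncol(expr),
        "labels must match the number of samples")
  check(leukocyte_label %in% compartment_labels, "leukocyte compartment not found")
  patients <- unique(patient_ids)
  for (p in patients) {
    if (!any(compartment_labels == leukocyte_label & patient_ids == p)) {
      stop(sprintf("patient '%s' has no leukocyte (%s) sample", p, leukocyte_label),
           call. = FALSE)
    }
  }
  genes <- genes %||% rownames(expr)
  present <- genes[genes %in% rownames(expr)]
  sub <- expr[present, , drop = FALSE]

  if (length(present) == 0L) {
    evidence <- data.frame(gene = genes, max_ratio = NA_real_,
                           which_compartment = NA_character_, p = NA_real_,
                           fail = FALSE, stringsAsFactors = FALSE)
    return(structure(character(0), evidence = evidence))
  }

  # per-patient leukocyte reference (averaged over replicates)
  leuko <- vapply(patients, function(p) {
    rowMeans(sub[, compartment_labels == leukocyte_label & patient_ids == p,
                 drop = FALSE])
  }, numeric(length(present)))
  leuko <- matrix(leuko, nrow = length(present))

  comps <- setdiff(unique(compartment_labels), leukocyte_label)
  max_ratio <- rep(-Inf, length(present))
  which_comp <- rep(NA_character_, length(present))
  p_at_max <- rep(NA_real_, length(present))
  fail_present <- rep(FALSE, length(present))
  for (cc in comps) {
    comp_expr <- vapply(patients, function(p) {
      idx <- compartment_labels == cc & patient_ids == p
      if (!any(idx)) return(rep(NA_real_, length(present)))
      rowMeans(sub[, idx, drop = FALSE])
    }, numeric(length(present)))
    comp_expr <- matrix(comp_expr, nrow = length(present))
    lr <- log((comp_expr + eps) / (leuko + eps))
    npat <- rowSums(!is.na(lr))
    mean_ratio <- rowMeans(exp(lr), na.rm = TRUE)
    mlr <- rowMeans(lr, na.rm = TRUE)
    sdlr <- apply(lr, 1L, stats::sd, na.rm = TRUE)
    tstat <- mlr / (sdlr / sqrt(npat))
    pvals <- stats::pt(tstat, df = npat - 1L, lower.tail = FALSE)
    pvals[!is.finite(tstat) & mlr > 0] <- 0   # identical positive log-ratios
    pvals[is.na(pvals)] <- 1
    this_fail <- mean_ratio > 1 & (!significance | pvals < alpha)
    fail_present <- fail_present | this_fail
    upd <- mean_ratio > max_ratio
    which_comp[upd] <- cc
    p_at_max[upd] <- pvals[upd]
    max_ratio[upd] <- mean_ratio[upd]
  }
  evidence <- data.frame(
    gene = genes,
    max_ratio = max_ratio[match(genes, present)],
    which_compartment = which_comp[match(genes, present)],
    p = p_at_max[match(genes, present)],
    fail = genes %in% present[fail_present],
    stringsAsFactors = FALSE
  )
  structure(evidence$gene[evidence$fail], evidence = evidence)
}

#' Single-cell specificity classification
#'
#' Classifies genes by their expression pattern across single-cell types:
#' * `specific`: target-type mean at least `ratio_cut` times the largest
#'   non-target mean *and* expressed in at least `frac_cut` of target cells;
#' * `non_specific`: at least `k` non-target types with mean at or above
#'   `1/ratio_cut` of the target mean (promiscuous expression);
#' * `high_basal`: everything else (e.g. high in the target but with moderate
#'   expression in a single other type);
#' * `unevaluable`: gene absent from the matrix (recorded, never dropped).
#' Expression is library-normalized (CPM) per cell before averaging.
#'
#' @param sc_counts genes x cells count matrix (dense or sparse).
#' @param cell_labels cell type per cell; must include `target`.
#' @param genes genes to classify.
#' @param target target cell type (default `"NK"`).
#' @param ratio_cut specificity fold threshold (default 2).
#' @param frac_cut minimum fraction of target cells expressing (default 0.25).
#' @param k number of promiscuous types triggering `non_specific` (default 2).
#' @return data frame of class `sc_classification` with columns `gene`,
#'   `class`, `target_mean`, `max_other_mean`, `target_frac`, `n_other_high`.
#' @export
sc_specificity_classify <- function(sc_counts, cell_labels, genes,
                                    target = "NK", ratio_cut = 2,
                                    frac_cut = 0.25, k = 2L) {
  check_matrix(sc_counts, "single-cell count matrix")
  cell_labels <- as.character(cell_labels)
  check(length(cell_labels) == ncol(sc_counts), "cell_labels must match cells")
  check(target %in% cell_labels, sprintf("target label '%s' not found", target))
  lib <- Matrix::colSums(sc_counts)
  scale <- ifelse(lib > 0, 1e6 / lib, 0)
  present <- genes[genes %in% rownames(sc_counts)]
  if (length(present) == 0L) {
    out <- data.frame(gene = genes, class = "unevaluable",
                      target_mean = NA_real_, max_other_mean = NA_real_,
                      target_frac = NA_real_, n_other_high = NA_integer_,
                      stringsAsFactors = FALSE)
    class(out) <- c("sc_classification", "data.frame")
    return(out)
  }
  sub <- as.matrix(sc_counts[present, , drop = FALSE])
  norm <- sweep(sub, 2L, scale, "*")
  types <- unique(cell_labels)
  mean_by <- vapply(types, function(tp) rowMeans(norm[, cell_labels == tp, drop = FALSE]),
                    numeric(length(present)))
  frac_by <- vapply(types, function(tp) rowMeans(sub[, cell_labels == tp, drop = FALSE] > 0),
                    numeric(length(present)))
  if (length(present) == 1L) {
    mean_by <- matrix(mean_by, nrow = 1L, dimnames = list(present, types))
    frac_by <- matrix(frac_by, nrow = 1L, dimnames = list(present, types))
  }
  t_mean <- mean_by[, target]
  o_mean <- mean_by[, setdiff(types, target), drop = FALSE]
  max_other <- apply(o_mean, 1L, max)
  n_other_high <- rowSums(o_mean >= t_mean / ratio_cut)
  t_frac <- frac_by[, target]

  cls <- ifelse(t_mean >= ratio_cut * max_other & t_frac >= frac_cut, "specific",
                ifelse(n_other_high >= k, "non_specific", "high_basal"))
  i <- match(genes, present)
  out <- data.frame(
    gene = genes,
    class = ifelse(genes %in% present, unname(cls)[i], "unevaluable"),
    target_mean = unname(t_mean)[i],
    max_other_mean = unname(max_other)[i],
    target_frac = unname(t_frac)[i],
    n_other_high = unname(n_other_high)[i],
    stringsAsFactors = FALSE
  )
  class(out) <- c("sc_classification", "data.frame")
  out
}

#' Cascade configuration
#'
#' Stage toggles and thresholds for [apply_cascade()].
#'
#' @param target target cell type.
#' @param median,tumour,stromal,sc logical stage toggles.
#' @param stromal_significance require the paired significance gate in the
#'   stromal filter (default TRUE).
#' @param stromal_alpha stromal test level.
#' @param ratio_cut,frac_cut,k single-cell classification thresholds.
#' @return named list of class `cascade_config`.
#' @export
cascade_config <- function(target = "NK", median = TRUE, tumour = TRUE,
                           stromal = TRUE, sc = TRUE,
                           stromal_significance = TRUE, stromal_alpha = 0.05,
                           ratio_cut = 2, frac_cut = 0.25, k = 2L) {
  out <- list(target = target, median = median, tumour = tumour,
              stromal = stromal, sc = sc,
              stromal_significance = stromal_significance,
              stromal_alpha = stromal_alpha,
              ratio_cut = ratio_cut, frac_cut = frac_cut, k = k)
  class(out) <- "cascade_config"
  out
}

#' Apply the specificity-filtration cascade
#'
#' Sequentially refines a candidate gene set: immune median-dominance filter
#' (per dataset, passes intersected), tumour cell-line filter (failing genes
#' unioned across panels), stromal-compartment filter, then single-cell
#' classification (removing `non_specific` genes). Every decision and its
#' numeric evidence is recorded in a per-gene ledger.
#'
#' @param candidates character vector of candidate genes (e.g. the union-DEG
#'   output of [merge_union_degs()]).
#' @param immune_datasets list of `list(norm =, labels =)` sorted-immune
#'   reference datasets.
#' @param line_panels list of tumour cell-line matrices.
#' @param compartments `list(expr =, labels =, patients =)` for the stromal
#'   filter, or `NULL` to skip.
#' @param sc_data `list(counts =, labels =)` for single-cell classification,
#'   or `NULL` to skip.
#' @param config a [cascade_config()].
#' @param nk_reference optional genes x samples matrix of target-type samples
#'   for the tumour filter; defaults to the target columns of the first
#'   immune dataset.
#' @return list of class `filter_cascade` with elements `signature`
#'   (retained genes) and `ledger` (per-gene data frame ending in
#'   `final_status`).
#' @export
apply_cascade <- function(candidates, immune_datasets, line_panels = list(),
                          compartments = NULL, sc_data = NULL,
                          config = cascade_config(), nk_reference = NULL) {
  candidates <- normalize_symbols(as.character(candidates))
  ledger <- data.frame(gene = candidates, stringsAsFactors = FALSE)
  ledger$final_status <- rep("retained", length(candidates))
  if (length(candidates) == 0L) {
    out <- list(signature = character(0), ledger = ledger, config = config)
    class(out) <- "filter_cascade"
    return(out)
  }
  active <- candidates
  mark_removed <- function(ledger, removed, stage) {
    idx <- ledger$gene %in% removed & ledger$final_status == "retained"
    ledger$final_status[idx] <- paste0("removed:", stage)
    ledger
  }

  # stage: immune median dominance, intersected across datasets
  if (isTRUE(config$median) && length(immune_datasets) > 0L) {
    pass <- active
    worst_margin <- rep(Inf, length(candidates))
    med_nk <- rep(NA_real_, length(candidates))
    med_other <- rep(NA_real_, length(candidates))
    for (ds in immune_datasets) {
      res <- median_specificity_filter(ds$norm, ds$labels, target = config$target,
                                       genes = active)
      ev <- attr(res, "evidence")
      margin <- ev$median_target - ev$median_other_max
      i <- match(ev$gene, candidates)
      upd <- is.na(worst_margin[i]) | (!is.na(margin) & margin < worst_margin[i])
      upd[is.na(upd)] <- TRUE
      med_nk[i][upd] <- ev$median_target[upd]
      med_other[i][upd] <- ev$median_other_max[upd]
      worst_margin[i][upd] <- margin[upd]
      pass <- intersect(pass, res)
    }
    ledger$median_nk <- med_nk
    ledger$median_other_max <- med_other
    ledger$median_pass <- ledger$gene %in% pass
    ledger <- mark_removed(ledger, setdiff(active, pass), "median")
    active <- pass
  }

  # stage: tumour cell lines, union of failing genes across panels
  if (isTRUE(config$tumour) && length(line_panels) > 0L && length(active) > 0L) {
    if (is.null(nk_reference)) {
      check(length(immune_datasets) > 0L,
            "tumour filter needs nk_reference or an immune dataset")
      ds <- immune_datasets[[1]]
      nk_reference <- ds$norm[, ds$labels == config$target, drop = FALSE]
    }
    failing <- character(0)
    nk_med <- rep(NA_real_, length(candidates))
    line_med <- rep(NA_real_, length(candidates))
    for (panel in line_panels) {
      res <- tumour_line_filter(nk_reference, panel, genes = active)
      ev <- attr(res, "evidence")
      i <- match(ev$gene, candidates)
      nk_med[i] <- ev$nk_median
      line_med[i] <- pmax(line_med[i], ev$line_median, na.rm = TRUE)
      failing <- union(failing, res)
    }
    ledger$nk_median <- nk_med
    ledger$line_median_max <- line_med
    ledger$line_fail <- ledger$gene %in% failing
    ledger <- mark_removed(ledger, failing, "tumour")
    active <- setdiff(active, failing)
  }

  # stage: stromal compartments
  if (isTRUE(config$stromal) && !is.null(compartments) && length(active) > 0L) {
    res <- stromal_filter(compartments$expr, compartments$labels,
                          compartments$patients,
                          leukocyte_label = compartments$leukocyte %||% "CD45",
                          genes = active,
                          significance = config$stromal_significance,
                          alpha = config$stromal_alpha)
    ev <- attr(res, "evidence")
    i <- match(ev$gene, candidates)
    ledger$max_compartment_ratio <- NA_real_
    ledger$max_compartment_ratio[i] <- ev$max_ratio
    ledger$stromal_fail <- ledger$gene %in% res
    ledger <- mark_removed(ledger, res, "stromal")
    active <- setdiff(active, res)
  }

  # stage: single-cell specificity classes (remove non_specific)
  if (isTRUE(config$sc) && !is.null(sc_data) && length(active) > 0L) {
    cls <- sc_specificity_classify(sc_data$counts, sc_data$labels, genes = active,
                                   target = config$target,
                                   ratio_cut = config$ratio_cut,
                                   frac_cut = config$frac_cut, k = config$k)
    ledger$sc_class <- cls$class[match(ledger$gene, cls$gene)]
    removed <- cls$gene[cls$class == "non_specific"]
    ledger <- mark_removed(ledger, removed, "sc")
    active <- setdiff(active, removed)
  }

  if (length(active) == 0L) {
    warning("cascade removed every candidate gene", call. = FALSE)
  }
  # keep final_status as last column
  ledger <- ledger[, c(setdiff(names(ledger), "final_status"), "final_status")]
  out <- list(signature = active, ledger = ledger, config = config)
  class(out) <- "filter_cascade"
  out
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat(sprintf("Specificity-filtration cascade: %d candidates -> %d retained\n",
              nrow(x$ledger), length(x$signature)))
  if (nrow(x$ledger) > 0L) {
    print(table(x$ledger$final_status))
  }
  invisible(x)
}
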