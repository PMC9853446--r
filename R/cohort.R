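# NK-high vs NK-low cohort comparison: differential expression between
# score strata, cross-cohort DEG overlap, logFC concordance, and gene-set
# enrichment (competitive rank-sum and hypergeometric over-representation).

#' Differential expression between score-high and score-low samples
#'
#' Subsets the cohort to the `high` and `low` strata (the `mid` group from a
#' decile stratification is excluded from the fit) and delegates to
#' [fit_moderated_de()] with `high` as the positive direction.
#'
#' @param norm genes x samples log2-CPM matrix.
#' @param groups group labels from [stratify()] (values in
#'   `high`/`low`/`mid`), one per column of `norm`.
#' @param lfc_cut,alpha DEG thresholds (defaults 1 and 0.05).
#' @return a `deg_table`.
#' @export
de_high_vs_low <- function(norm, groups, lfc_cut = 1, alpha = 0.05) {
  check_matrix(norm, "normalized matrix")
  groups <- as.character(groups)
  check(length(groups) == ncol(norm), "groups must match samples")
  keep <- groups %in% c("high", "low")
  check(any(groups == "high") && any(groups == "low"),
        "both high and low groups must be non-empty")
  fit_moderated_de(norm[, keep, drop = FALSE], groups[keep], group1 = "high",
                   lfc_cut = lfc_cut, alpha = alpha)
}

#' Overlap of DEG calls between two cohorts
#'
#' @param a,b lists with `up` and `down` character vectors (see
#'   [call_degs()]).
#' @return list with `shared_up`, `shared_down` and `counts`, a named vector
#'   of Venn counts (`up_a_only`, `up_shared`, `up_b_only`, and the same for
#'   down).
#' @export
overlap_degs <- function(a, b) {
  shared_up <- intersect(a$up, b$up)
  shared_down <- intersect(a$down, b$down)
  counts <- c(up_a_only = length(setdiff(a$up, b$up)),
              up_shared = length(shared_up),
              up_b_only = length(setdiff(b$up, a$up)),
              down_a_only = length(setdiff(a$down, b$down)),
              down_shared = length(shared_down),
              down_b_only = length(setdiff(b$down, a$down)))
  list(shared_up = shared_up, shared_down = shared_down, counts = counts)
}

#' Spearman concordance of log-fold-changes between two cohorts
#'
#' Rank correlation of per-gene log2FC over the shared genes, with the usual
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df for
#' the p-value. Being a rank statistic it is invariant under strictly
#' monotone transforms of either table's logFCs.
#'
#' @param table_a,table_b `deg_table`s (or data frames with `gene` and
#'   `log2FC`).
#' @return list of class `corr_stat` with `rho`, `p`, `n`.
#' @export
logfc_concordance <- function(table_a, table_b) {
  shared <- intersect(table_a$gene, table_b$gene)
  n <- length(shared)
  check(n >= 3L, "need at least 3 shared genes")
  x <- table_a$log2FC[match(shared, table_a$gene)]
  y <- table_b$log2FC[match(shared, table_b$gene)]
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(rho = rho, p = p, n = n), class = "corr_stat")
}

#' @export
print.corr_stat <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.3g)\n", x$rho, x$n, x$p))
  invisible(x)
}

#' Competitive gene-set test (rank-sum)
#'
#' Asks whether the gene-level statistics of a set rank higher (or lower)
#' than those of the remaining genes: a two-sided Wilcoxon rank-sum test
#' using the normal approximation with tie correction and no continuity
#' correction. No inter-gene correlation adjustment is applied.
#'
#' @param stats named numeric vector of per-gene statistics (e.g. moderated
#'   t values).
#' @param set character vector of set genes.
#' @return list of class `enrichment_result` with `statistic` (the rank-sum
#'   z), `direction` (`"up"`/`"down"`), `p`, `n_set`, `n_rest`.
#' @export
competitive_set_test <- function(stats, set) {
  check(is.numeric(stats) && !is.null(names(stats)), "stats must be a named numeric vector")
  in_set <- names(stats) %in% set
  n1 <- sum(in_set); n2 <- sum(!in_set)
  check(n1 >= 2L && n2 >= 2L, "need at least 2 genes inside and outside the set")
  n <- n1 + n2
  r <- rank(stats)
  r1 <- sum(r[in_set])
  mu <- n1 * (n + 1) / 2
  ties <- table(stats)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (r1 - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(statistic = z,
                 direction = if (z >= 0) "up" else "down",
                 p = p, n_set = n1, n_rest = n2),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Competitive set test: z = %.3f (%s), p = %.3g (n_set = %d)\n",
              x$statistic, x$direction, x$p, x$n_set))
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' One-sided tail probability of observing at least the seen overlap between
#' a DEG set and each annotation term, within a fixed gene universe;
#' BH-adjusted across terms. Terms with no gene in the universe are skipped
#' with a warning.
#'
#' @param deg_set character vector of selected genes (must lie in `universe`).
#' @param annotation named list mapping term names to gene sets (e.g. read
#'   from GMT).
#' @param universe character vector of all testable genes.
#' @return data frame with columns `term`, `overlap`, `set_size`,
#'   `deg_size`, `p`, `p_adj`, sorted by `p`.
#' @export
overrepresentation_test <- function(deg_set, annotation, universe) {
  universe <- unique(as.character(universe))
  deg_set <- unique(as.character(deg_set))
  check(all(deg_set %in% universe), "deg_set must be a subset of the universe")
  check(is.list(annotation) && length(annotation) > 0L && !is.null(names(annotation)),
        "annotation must be a non-empty named list")
  sizes <- integer(0); overlaps <- integer(0); terms <- character(0)
  ps <- numeric(0)
  n_u <- length(universe)
  n_d <- length(deg_set)
  for (tm in names(annotation)) {
    term_genes <- intersect(annotation[[tm]], universe)
    if (length(term_genes) == 0L) {
      warning(sprintf("term '%s' has no gene in the universe; skipped", tm),
              call. = FALSE)
      next
    }
    x <- length(intersect(term_genes, deg_set))
    p <- stats::phyper(x - 1L, length(term_genes), n_u - length(term_genes),
                       n_d, lower.tail = FALSE)
    terms <- c(terms, tm)
    sizes <- c(sizes, length(term_genes))
    overlaps <- c(overlaps, x)
    ps <- c(ps, p)
  }
  check(length(terms) > 0L, "no testable annotation term")
  out <- data.frame(term = terms, overlap = overlaps, set_size = sizes,
                    deg_size = n_d, p = ps, p_adj = adjust_bh(ps),
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Barcode-plot positions of a gene set
#'
#' Sorted rank positions (ascending by statistic) of the set genes within the
#' universe, exportable for external barcode plotting.
#'
#' @param stats named numeric vector of per-gene statistics.
#' @param set character vector of set genes.
#' @return integer vector of sorted positions.
#' @export
barcode_positions <- function(stats, set) {
  check(is.numeric(stats) && !is.null(names(stats)), "stats must be a named numeric vector")
  sort(which(names(sort(stats)) %in% set))
}
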