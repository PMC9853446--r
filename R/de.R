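# Differential-expression engine: CPM normalization, low-expression
# filtering, a variance-moderated two-group t-test with empirical-Bayes
# shrinkage of gene-wise variances, BH adjustment, DEG calling and the
# pairwise NK-versus-each-type sweep.

#' Counts per million
#'
#' @param counts non-negative genes x samples count matrix.
#' @return matrix of CPM values.
#' @export
cpm <- function(counts) {
  check_matrix(counts, "count matrix")
  lib <- colSums(counts)
  check(all(lib > 0), "zero library size: at least one sample has no counts")
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Keeps genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples. Low-abundance genes carry almost no information for two-group
#' testing and destabilise variance estimation, so they are removed before
#' normalization.
#'
#' @param counts genes x samples count matrix.
#' @param min_cpm minimum CPM (default 1).
#' @param min_samples minimum number of samples meeting `min_cpm`.
#' @return character vector of retained gene identifiers.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 2L) {
  check_matrix(counts, "count matrix")
  check(all(counts >= 0), "counts must be non-negative")
  check(min_samples <= ncol(counts), "min_samples exceeds the number of samples")
  keep <- rowSums(cpm(counts) >= min_cpm) >= min_samples
  if (!any(keep)) {
    stop("all genes removed by the low-expression filter; lower min_cpm or min_samples",
         call. = FALSE)
  }
  rownames(counts)[keep]
}

#' Log2 counts-per-million
#'
#' Computes `log2(count / library_size * 1e6 + pseudo)`. The pseudo-count
#' (default 0.5) stabilises the log at zero counts and is recorded as an
#' attribute.
#'
#' @param counts genes x samples count matrix.
#' @param pseudo positive pseudo-count added on the CPM scale.
#' @return genes x samples matrix of log2-CPM values with attributes
#'   `pseudo` and `units = "logCPM"`.
#' @export
to_log_cpm <- function(counts, pseudo = 0.5) {
  check(is_scalar_num(pseudo) && pseudo > 0, "pseudo must be a positive number")
  out <- log2(cpm(counts) + pseudo)
  structure(out, pseudo = pseudo, units = "logCPM")
}

# Inverse of trigamma by Newton iteration on 1/trigamma (convex scale).
trigamma_inverse <- function(y) {
  check(is_scalar_num(y) && y > 0, "trigamma_inverse needs a positive value")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Method-of-moments fit of the scaled inverse-chi-square prior (d0, s0^2)
# from gene-wise variances s2 on d residual df, matching mean and variance
# of log s2. Under the hierarchical model log s2 = log s0^2 +
# log chisq_d/d - log chisq_d0/d0, so
#   Var(log s2) = trigamma(d/2) + trigamma(d0/2)
#   E(log s2)   = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2).
estimate_prior_var <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L) {
    # too few informative genes for a stable moment fit
    d0 <- 10
    s02 <- if (any(ok)) mean(s2[ok]) else 1
    return(list(d0 = d0, s02 = s02))
  }
  z <- log(s2[ok])
  excess <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    # variances more concentrated than a chi-square on d df: infinite prior df
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group differential expression
#'
#' Per gene: `log2FC` is the mean difference on the log2-CPM scale
#' (`group1 - group2`); the pooled residual variance `s2` on
#' `d = n1 + n2 - 2` df is shrunk towards a prior `s02` with prior df `d0`
#' estimated from the whole ensemble of gene variances by moment matching on
#' `log s2`; the moderated t is the mean difference over the posterior
#' standard error and is referred to a t distribution on `d0 + d` df.
#' Borrowing variance information across genes is what makes small-replicate
#' RNA-seq contrasts testable.
#'
#' @param norm genes x samples matrix on the log2-CPM scale
#'   (see [to_log_cpm()]).
#' @param groups vector of two group labels, one per sample.
#' @param group1 label treated as the positive direction of `log2FC`;
#'   defaults to the first label encountered.
#' @param d0 optional override of the prior df: `0` gives the ordinary
#'   two-sample t-test, `Inf` a pooled-variance z-like test; `NULL`
#'   (default) estimates it from the data.
#' @param lfc_cut,alpha thresholds used to fill the `call` column
#'   (see [call_degs()]).
#' @return data frame of class `deg_table` with columns `gene`, `log2FC`,
#'   `t`, `p`, `p_adj`, `call`; attributes `d0`, `s02`, `df_total`.
#' @export
fit_moderated_de <- function(norm, groups, group1 = NULL, d0 = NULL,
                             lfc_cut = 1, alpha = 0.05) {
  check_matrix(norm, "normalized matrix")
  check(length(groups) == ncol(norm), "groups must match the number of samples")
  groups <- as.character(groups)
  lev <- unique(groups)
  check(length(lev) == 2L, "exactly two groups are required")
  group1 <- group1 %||% lev[[1]]
  check(group1 %in% lev, "group1 is not one of the group labels")
  group2 <- setdiff(lev, group1)
  i1 <- groups == group1
  i2 <- groups == group2
  n1 <- sum(i1); n2 <- sum(i2)
  check(n1 >= 2L && n2 >= 2L, "each group needs at least 2 samples")

  x1 <- norm[, i1, drop = FALSE]
  x2 <- norm[, i2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  lfc <- m1 - m2
  d <- n1 + n2 - 2L
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- rss / d

  if (is.null(d0)) {
    prior <- estimate_prior_var(s2, d)
    d0 <- prior$d0
    s02 <- prior$s02
  } else {
    check(is_scalar_num(d0) || identical(d0, Inf), "d0 must be a single number or Inf")
    check(d0 >= 0, "d0 must be non-negative")
    s02 <- if (any(s2 > 0)) mean(s2[s2 > 0]) else 1
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- data.frame(gene = rownames(norm), log2FC = lfc, t = tstat, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- adjust_bh(out$p)
  out$call <- ifelse(out$p_adj < alpha & out$log2FC > lfc_cut, "up",
                     ifelse(out$p_adj < alpha & out$log2FC < -lfc_cut, "down", "ns"))
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_total") <- df_total
  attr(out, "groups") <- c(group1 = group1, group2 = group2)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("DEG table: %d genes, %s vs %s (d0 = %.3g)\n",
              nrow(x), g[["group1"]], g[["group2"]],
              attr(x, "d0") %||% NA_real_))
  cat(sprintf("  up: %d  down: %d  ns: %d\n",
              sum(x$call == "up"), sum(x$call == "down"), sum(x$call == "ns")))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone in rank and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`; NA/NaN are rejected.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) {
  check(is.numeric(p) && length(p) >= 1L, "p must be a numeric vector")
  check(!anyNA(p), "p contains NA/NaN values")
  check(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds matching the usual reporting convention:
#' `log2FC > lfc_cut` (up) or `log2FC < -lfc_cut` (down) *and*
#' `p_adj < alpha`.
#'
#' @param table a `deg_table`.
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
call_degs <- function(table, lfc_cut = 1, alpha = 0.05) {
  check(all(c("gene", "log2FC", "p_adj") %in% names(table)),
        "table must have gene, log2FC and p_adj columns")
  list(up = table$gene[table$log2FC > lfc_cut & table$p_adj < alpha],
       down = table$gene[table$log2FC < -lfc_cut & table$p_adj < alpha])
}

#' Pairwise target-versus-each-type up-regulation sweep
#'
#' Runs one moderated two-group contrast of the target cell type against each
#' other cell type and returns the up-in-target DEG set per comparison. Feed
#' the result (per dataset) to [merge_union_degs()].
#'
#' @param norm genes x samples log2-CPM matrix.
#' @param cell_labels cell-type label per sample.
#' @param target target cell type (default `"NK"`).
#' @param lfc_cut,alpha DEG thresholds.
#' @return named list mapping each other cell type to the character vector of
#'   genes up-regulated in the target.
#' @export
pairwise_nk_degs <- function(norm, cell_labels, target = "NK",
                             lfc_cut = 1, alpha = 0.05) {
  check_matrix(norm, "normalized matrix")
  cell_labels <- as.character(cell_labels)
  check(length(cell_labels) == ncol(norm), "cell_labels must match samples")
  check(target %in% cell_labels, sprintf("target label '%s' not found", target))
  others <- setdiff(unique(cell_labels), target)
  check(length(others) >= 1L, "need at least one non-target cell type")
  out <- lapply(others, function(ct) {
    idx <- cell_labels %in% c(target, ct)
    fit <- fit_moderated_de(norm[, idx, drop = FALSE], cell_labels[idx],
                            group1 = target, lfc_cut = lfc_cut, alpha = alpha)
    call_degs(fit, lfc_cut = lfc_cut, alpha = alpha)$up
  })
  names(out) <- others
  out
}
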