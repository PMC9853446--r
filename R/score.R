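# Rank-based single-sample gene-set scoring and cohort stratification.
#
# For one sample, genes are ranked ascending by expression (ties averaged)
# and the signature score is the normalized mean rank of the signature genes:
#   score = (mean_rank - (ns + 1) / 2) / (N - ns)
# with N ranked genes and ns signature genes present. The score lies in
# [0, 1]: 0 when the signature occupies the bottom ns ranks, 1 when it
# occupies the top ns, and it depends on the data only through within-sample
# ranks, so any strictly increasing per-sample transform leaves it unchanged.

#' Rank genes within one sample
#'
#' Ascending ranks `1..N`, ties receiving the average rank.
#'
#' @param expression named numeric vector (one sample).
#' @return named rank vector.
#' @export
rank_sample <- function(expression) {
  check(is.numeric(expression) && length(expression) >= 2L,
        "need a numeric vector of at least 2 genes")
  check(!anyNA(expression), "expression contains NA/NaN")
  rank(expression, ties.method = "average")
}

#' Score one sample against a signature
#'
#' @param ranks rank vector from [rank_sample()] with gene names.
#' @param signature character vector of signature genes; genes absent from
#'   the ranked universe are dropped (and counted via `n_used`).
#' @return the normalized score (numeric scalar) with attributes `mean_rank`
#'   and `n_used`.
#' @export
score_sample <- function(ranks, signature) {
  check(!is.null(names(ranks)), "ranks must be named by gene")
  sig <- intersect(signature, names(ranks))
  ns <- length(sig)
  check(ns >= 1L, "no signature gene present in the ranked universe")
  n <- length(ranks)
  check(ns < n, "signature must be smaller than the ranked universe")
  mean_rank <- mean(ranks[sig])
  score <- (mean_rank - (ns + 1) / 2) / (n - ns)
  structure(score, mean_rank = mean_rank, n_used = ns)
}

#' Score every sample of a cohort
#'
#' Scores are rank-based and therefore invariant to any strictly increasing
#' per-sample transform of expression, so the matrix may be on any scale
#' (counts, CPM, TPM, log).
#'
#' @param mat genes x samples expression matrix.
#' @param signature character vector of signature genes. If fewer than
#'   `min_frac` of them are present an error is raised; if some (but enough)
#'   are missing a warning reports the count.
#' @param min_frac minimum fraction of signature genes that must be present
#'   (default 0.5).
#' @return data frame of class `score_result` with columns `sample`, `score`,
#'   `mean_rank`, `n_signature_genes_used`.
#' @export
score_cohort <- function(mat, signature, min_frac = 0.5) {
  check_matrix(mat, "expression matrix")
  signature <- unique(as.character(signature))
  present <- intersect(signature, rownames(mat))
  check(length(present) / length(signature) >= min_frac,
        sprintf("only %d/%d signature genes present (< %.0f%%)",
                length(present), length(signature), 100 * min_frac))
  if (length(present) < length(signature)) {
    warning(sprintf("%d/%d signature genes absent from the matrix; scoring on %d",
                    length(signature) - length(present), length(signature),
                    length(present)), call. = FALSE)
  }
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    s <- score_sample(rank_sample(mat[, j]), present)
    c(score = as.numeric(s), mean_rank = attr(s, "mean_rank"))
  }, numeric(2))
  out <- data.frame(sample = colnames(mat), score = scores["score", ],
                    mean_rank = scores["mean_rank", ],
                    n_signature_genes_used = length(present),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("score_result", "data.frame")
  out
}

#' Stratify samples by signature score
#'
#' Two conventions: `"decile"` marks the top and bottom `floor(q * n)` samples
#' `high`/`low` and everything else `mid` (used upstream of NK-high vs NK-low
#' differential expression); `"median"` splits at the median with
#' strictly-above going `high` and ties at the median going `low` (used for
#' survival analysis). Decile ties at the boundary are broken by stable sample
#' order.
#'
#' @param scores numeric vector of scores or a `score_result`.
#' @param method `"decile"` or `"median"`.
#' @param q tail fraction for the decile method (default 0.10).
#' @return character vector of group labels (`high`, `low`, `mid`) in input
#'   order, named by sample when available.
#' @export
stratify <- function(scores, method = c("decile", "median"), q = 0.10) {
  method <- match.arg(method)
  nms <- NULL
  if (inherits(scores, "score_result")) {
    nms <- scores$sample
    scores <- scores$score
  } else if (!is.null(names(scores))) {
    nms <- names(scores)
  }
  check(is.numeric(scores) && !anyNA(scores), "scores must be numeric without NA")
  n <- length(scores)
  if (method == "median") {
    check(n >= 2L, "median stratification needs at least 2 samples")
    grp <- ifelse(scores > stats::median(scores), "high", "low")
  } else {
    check(is_scalar_num(q) && q > 0 && q < 0.5, "q must lie in (0, 0.5)")
    check(n >= ceiling(1 / q), sprintf("decile stratification needs >= %d samples",
                                       ceiling(1 / q)))
    k <- floor(q * n)
    ord <- order(scores)  # stable for ties
    grp <- rep("mid", n)
    grp[ord[seq_len(k)]] <- "low"
    grp[ord[seq.int(n - k + 1L, n)]] <- "high"
  }
  names(grp) <- nms
  grp
}
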