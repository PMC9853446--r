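# Candidate-marker collation: GMT I/O, source-membership tables,
# intersection structure and the union-DEG merge criterion.

#' Normalize gene symbols
#'
#' Uppercases symbols, strips surrounding whitespace, drops anything after a
#' `"|"` separator (common in pipe-annotated identifiers) and removes empty
#' strings. Duplicates are collapsed keeping the first occurrence.
#'
#' @param x character vector of gene symbols.
#' @return character vector of cleaned, unique symbols.
#' @export
normalize_symbols <- function(x) {
  check(is.character(x), "symbols must be a character vector")
  x <- sub("\\|.*$", "", x)
  x <- toupper(trimws(x))
  x <- x[nzchar(x)]
  x[!duplicated(x)]
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are
#' normalized with [normalize_symbols()] and duplicates within a line are
#' collapsed.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (one element per gene set).
#' @export
read_gmt <- function(path) {
  check(file.exists(path), sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  check(length(lines) > 0L, "GMT file is empty")
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields", i),
           call. = FALSE)
    }
    genes <- normalize_symbols(fields[-c(1L, 2L)])
    if (length(genes) == 0L) {
      stop(sprintf("malformed GMT line %d: empty gene list", i), call. = FALSE)
    }
    nms[[i]] <- fields[[1]]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written to every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  check(is.list(sets) && length(sets) > 0L && !is.null(names(sets)),
        "sets must be a non-empty named list")
  lines <- vapply(seq_along(sets), function(i) {
    genes <- normalize_symbols(sets[[i]])
    check(length(genes) > 0L, sprintf("gene set '%s' is empty", names(sets)[i]))
    paste(c(names(sets)[i], description, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Collate gene sources into a candidate membership table
#'
#' Builds the per-gene source-membership ledger over the union of all input
#' sets: one logical column per source plus `sum_of_sources`, the number of
#' sources containing each gene. This is the table behind upset-style
#' intersection counting of partially overlapping marker sources.
#'
#' @param sets named list of character vectors (gene sets).
#' @return data frame with columns `gene`, one logical column per source and
#'   `sum_of_sources`; class `"candidate_table"`.
#' @export
collate_sources <- function(sets) {
  check(is.list(sets) && length(sets) >= 1L && !is.null(names(sets)),
        "need a named list of at least one gene set")
  sets <- lapply(sets, normalize_symbols)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  out <- data.frame(gene = universe, member, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$sum_of_sources <- as.integer(rowSums(member))
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Exclusive intersection counts of a candidate table
#'
#' Counts genes per exact source-membership pattern (the red intersection bars
#' of an upset plot). Patterns partition the union, so counts sum to the table
#' size.
#'
#' @param table a `candidate_table` from [collate_sources()].
#' @return data frame with columns `pattern` (binary string in source-column
#'   order), `sources` (comma-separated names), `n_sources` and `n_genes`,
#'   sorted by decreasing `n_genes`.
#' @export
intersection_counts <- function(table) {
  check(inherits(table, "candidate_table") && nrow(table) > 0L,
        "need a non-empty candidate_table")
  src_cols <- setdiff(names(table), c("gene", "sum_of_sources"))
  member <- as.matrix(table[, src_cols, drop = FALSE])
  pattern <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), n_genes = as.integer(tab),
                    stringsAsFactors = FALSE)
  bits <- strsplit(out$pattern, "")
  out$sources <- vapply(bits, function(b) paste(src_cols[b == "1"], collapse = ","),
                        character(1))
  out$n_sources <- vapply(bits, function(b) sum(b == "1"), integer(1))
  out <- out[order(-out$n_genes, out$pattern), c("pattern", "sources", "n_sources", "n_genes")]
  rownames(out) <- NULL
  out
}

#' Merge pairwise up-regulation sets with the union-DEG criterion
#'
#' A gene qualifies if, within at least one dataset, it is up-regulated in the
#' target cell type versus *every* other cell type compared in that dataset
#' (per-dataset intersection of pairwise up-sets, then union across datasets).
#'
#' @param pairwise_up list of datasets; each dataset is a named list mapping
#'   the other cell type to the character vector of genes up-regulated in the
#'   target versus that type.
#' @return character vector of union-DEG genes (sorted).
#' @export
merge_union_degs <- function(pairwise_up) {
  check(is.list(pairwise_up) && length(pairwise_up) >= 1L,
        "need at least one dataset of pairwise comparisons")
  per_dataset <- lapply(seq_along(pairwise_up), function(i) {
    ds <- pairwise_up[[i]]
    if (!is.list(ds) || length(ds) == 0L) {
      stop(sprintf("dataset %d has zero pairwise comparisons", i), call. = FALSE)
    }
    Reduce(intersect, lapply(ds, normalize_symbols))
  })
  sort(unique(unlist(per_dataset, use.names = FALSE)))
}
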