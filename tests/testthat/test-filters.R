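label_mat <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

test_that("median-dominance filter requires a strictly higher target median", {
  # gene A: NK median 5 vs others {3, 4}; gene B ties one other type at 5
  norm <- rbind(A = c(5, 5, 3, 3, 4, 4),
                B = c(5, 5, 5, 5, 2, 2))
  colnames(norm) <- sprintf("S%d", 1:6)
  labels <- c("NK", "NK", "T", "T", "B", "B")
  pass <- median_specificity_filter(norm, labels)
  expect_identical(as.character(pass), "A")
  ev <- attr(pass, "evidence")
  expect_false(ev$pass[ev$gene == "B"])  # tie fails (strict)
  expect_error(median_specificity_filter(norm, labels, target = "X"), "not found")
})

test_that("median filter matches a brute-force median comparison on random data", {
  withr::with_seed(31, {
    norm <- toy_matrix(120, 12)
    labels <- rep(c("NK", "T", "B"), each = 4)
    pass <- median_specificity_filter(norm, labels)
    meds <- sapply(c("NK", "T", "B"), function(l) {
      apply(norm[, labels == l], 1, median)
    })
    oracle <- rownames(norm)[meds[, "NK"] > pmax(meds[, "T"], meds[, "B"])]
    expect_identical(as.character(pass), oracle)
  })
})

test_that("tumour-line filter flags genes with line median above the NK median", {
  genes <- c("hot", "equal", "cold")
  nk <- label_mat(c(4, 4, 4,  5, 5, 5,  9, 9, 9), genes, paste0("NK", 1:3))
  lines <- label_mat(c(6, 6, 6,  5, 5, 5,  1, 1, 1), genes, paste0("L", 1:3))
  fail <- tumour_line_filter(nk, lines)
  expect_identical(as.character(fail), "hot")   # 6 > 4 fails
  ev <- attr(fail, "evidence")
  expect_false(ev$fail[ev$gene == "equal"])     # equal medians pass

  expect_error(tumour_line_filter(nk, label_mat(1, "other", "L1")),
               "empty intersection")
})

test_that("panels failing disjoint genes are unioned by the cascade stage", {
  genes <- c("G1", "G2", "G3")
  nk <- label_mat(rep(2, 9), genes, paste0("NK", 1:3))
  panel_a <- label_mat(c(9, 9, 9,  0, 0, 0,  0, 0, 0), genes, paste0("A", 1:3))
  panel_b <- label_mat(c(0, 0, 0,  9, 9, 9,  0, 0, 0), genes, paste0("B", 1:3))
  res <- apply_cascade(genes,
                       immune_datasets = list(),
                       line_panels = list(panel_a, panel_b),
                       config = cascade_config(median = FALSE, stromal = FALSE,
                                               sc = FALSE),
                       nk_reference = nk)
  expect_setequal(res$ledger$gene[res$ledger$line_fail], c("G1", "G2"))
  expect_identical(res$signature, "G3")
})

test_that("stromal filter combines a mean-ratio rule with a paired significance gate", {
  genes <- c("flat", "stromal", "noisy")
  patients <- rep(sprintf("P%d", 1:6), each = 2)
  comp <- rep(c("CD45", "FAP"), 6)
  samples <- paste(patients, comp, sep = "_")
  expr <- matrix(100, nrow = 3, ncol = 12, dimnames = list(genes, samples))
  expr["stromal", comp == "FAP"] <- 500                       # ratio 5
  noisy_ratios <- c(2, 0.5, 2.2, 0.45, 2.1, 0.52)             # mean ratio > 1, p large
  expr["noisy", comp == "FAP"] <- 100 * noisy_ratios

  fail <- stromal_filter(expr, comp, patients)
  expect_identical(as.character(fail), "stromal")
  ev <- attr(fail, "evidence")
  expect_false(ev$fail[ev$gene == "flat"])   # ratio 1 everywhere -> pass

  # paired-test oracle: the noisy gene's one-sided p exceeds alpha
  lr <- log((100 * noisy_ratios + 0.5) / (100 + 0.5))
  p_oracle <- t.test(lr, alternative = "greater")$p.value
  expect_gt(p_oracle, 0.05)
  expect_false("noisy" %in% fail)
  # with the gate off the mean-ratio rule alone flags it
  fail_nogate <- stromal_filter(expr, comp, patients, significance = FALSE)
  expect_true("noisy" %in% fail_nogate)

  expect_error(stromal_filter(expr[, -1], comp[-1], patients[-1]),
               "no leukocyte")
})

test_that("single-cell classification separates specific, promiscuous and basal genes", {
  genes <- c("nk_only", "uniform", "one_other", "absent")
  cells <- sprintf("C%02d", 1:30)
  labels <- rep(c("NK", "T", "Myeloid"), each = 10)
  counts <- matrix(0, nrow = 3, ncol = 30,
                   dimnames = list(genes[1:3], cells))
  counts["nk_only", labels == "NK"] <- 10
  counts["uniform", ] <- 5
  counts["one_other", labels == "NK"] <- 10
  counts["one_other", labels == "T"] <- 8   # within 2x of NK, single type
  cls <- sc_specificity_classify(counts, labels, genes)
  got <- setNames(cls$class, cls$gene)
  expect_identical(got[["nk_only"]], "specific")
  expect_identical(got[["uniform"]], "non_specific")
  expect_identical(got[["one_other"]], "high_basal")
  expect_identical(got[["absent"]], "unevaluable")
})

test_that("cascade with all filters disabled is the identity on candidates", {
  cands <- c("A", "B", "C")
  res <- apply_cascade(cands, immune_datasets = list(),
                       config = cascade_config(median = FALSE, tumour = FALSE,
                                               stromal = FALSE, sc = FALSE))
  expect_identical(res$signature, cands)
  expect_true(all(res$ledger$final_status == "retained"))
})

test_that("cascade on empty candidates returns an empty ledger without error", {
  res <- apply_cascade(character(0), immune_datasets = list())
  expect_length(res$signature, 0L)
  expect_identical(nrow(res$ledger), 0L)
})

test_that("cascade ledger partitions candidates and output is a candidate subset", {
  cfg <- tiny_config()
  im <- generate_sorted_immune(cfg)
  norm <- to_log_cpm(im$counts)
  lines <- generate_cell_lines(cfg, im$truth$planted_leaky_genes, n_lines = 10)
  comps <- generate_compartments(cfg, im$truth$planted_stromal_genes)
  sc <- generate_single_cell(cfg)
  cands <- c(im$truth$planted_nk_markers, rownames(norm)[1:20])
  res <- apply_cascade(unique(cands),
                       immune_datasets = list(list(norm = norm,
                                                   labels = im$annotation$cell_type)),
                       line_panels = list(to_log_cpm(lines)),
                       compartments = list(expr = cpm(comps$counts),
                                           labels = comps$annotation$compartment,
                                           patients = comps$annotation$patient),
                       sc_data = list(counts = sc$counts, labels = sc$labels))
  expect_true(all(res$signature %in% cands))
  expect_identical(sort(unique(c(res$signature,
                                 res$ledger$gene[res$ledger$final_status != "retained"]))),
                   sort(unique(normalize_symbols(cands))))
  expect_identical(res$ledger$gene[res$ledger$final_status == "retained"],
                   res$signature)
})

test_that("median filter is idempotent and shrinks when a contaminant type is added", {
  withr::with_seed(33, {
    norm <- toy_matrix(150, 12)
    labels <- rep(c("NK", "T", "B"), each = 4)
    pass1 <- median_specificity_filter(norm, labels)
    pass2 <- median_specificity_filter(norm, labels, genes = as.character(pass1))
    expect_identical(as.character(pass2), as.character(pass1))

    # add a contaminant cell type: pass set can only shrink
    contam <- toy_matrix(150, 4, seed = 99)
    colnames(contam) <- paste0("X", 1:4)
    norm2 <- cbind(norm, contam + 2)
    labels2 <- c(labels, rep("Contam", 4))
    pass3 <- median_specificity_filter(norm2, labels2)
    expect_true(all(pass3 %in% pass1))
  })
})
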