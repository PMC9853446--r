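make_counts <- function(mat) {
  dimnames(mat) <- list(sprintf("G%03d", seq_len(nrow(mat))),
                        sprintf("S%02d", seq_len(ncol(mat))))
  mat
}

test_that("low-expression filter keeps genes by the CPM-in-enough-samples rule", {
  counts <- make_counts(rbind(rep(0, 4), c(2, 2, 0, 0), rep(100, 4)))
  counts[3, ] <- 1e6 - colSums(counts[1:2, , drop = FALSE])  # library = 1e6
  kept <- filter_low_expression(counts, min_cpm = 1, min_samples = 2)
  expect_false("G001" %in% kept)       # all-zero gene removed
  expect_true("G002" %in% kept)        # CPM 2 in exactly min_samples samples

  expect_error(filter_low_expression(counts, min_cpm = 1e9, min_samples = 1),
               "all genes removed")

  withr::with_seed(3, {
    rnd <- make_counts(matrix(rnbinom(500 * 8, mu = 5, size = 1), 500, 8))
    rnd[1, ] <- rnd[1, ] + 1  # avoid an all-zero library edge
    kept <- filter_low_expression(rnd, min_cpm = 50, min_samples = 3)
    cpm_mat <- sweep(rnd, 2, colSums(rnd), "/") * 1e6
    oracle <- rownames(rnd)[rowSums(cpm_mat >= 50) >= 3]
    expect_identical(kept, oracle)
  })
})

test_that("log-CPM matches its definition and is invariant to joint library scaling", {
  counts <- make_counts(matrix(c(0, 1024, 1e6 - 1024, 10, 10, 1e6 - 20), 3, 2))
  norm <- to_log_cpm(counts, pseudo = 0.5)
  expect_equal(norm[1, 1], log2(0.5))
  expect_equal(as.numeric(to_log_cpm(counts, pseudo = 1e-9)[2, 1]), 10,
               tolerance = 1e-6)

  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 7  # scale all genes of one sample jointly
  expect_equal(to_log_cpm(scaled)[, 2], to_log_cpm(counts)[, 2])

  zero <- counts; zero[, 1] <- 0
  expect_error(to_log_cpm(zero), "library")
})

test_that("moderated t is antisymmetric under group swap", {
  norm <- toy_matrix(100, 8)
  groups <- rep(c("A", "B"), each = 4)
  f1 <- fit_moderated_de(norm, groups, group1 = "A")
  f2 <- fit_moderated_de(norm, groups, group1 = "B")
  expect_equal(f1$log2FC, -f2$log2FC)
  expect_equal(f1$t, -f2$t)
  expect_equal(f1$p, f2$p)
})

test_that("prior df limits recover the ordinary t-test and the pooled z-like test", {
  norm <- toy_matrix(50, 10, seed = 4)
  groups <- rep(c("A", "B"), each = 5)
  fit0 <- fit_moderated_de(norm, groups, group1 = "A", d0 = 0)
  for (g in c(1, 17, 50)) {
    ht <- t.test(norm[g, 1:5], norm[g, 6:10], var.equal = TRUE)
    expect_equal(fit0$t[g], unname(ht$statistic), tolerance = 1e-10)
    expect_equal(fit0$p[g], ht$p.value, tolerance = 1e-10)
  }
  fitInf <- fit_moderated_de(norm, groups, group1 = "A", d0 = Inf)
  # pooled variance: every gene shares one denominator
  denom <- fitInf$log2FC / fitInf$t
  expect_equal(max(denom) - min(denom), 0, tolerance = 1e-12)
})

test_that("moderated fit agrees with the limma empirical-Bayes reference", {
  skip_if_not_installed("limma")
  norm <- toy_matrix(300, 8, seed = 9)
  groups <- rep(c("A", "B"), each = 4)
  fit <- fit_moderated_de(norm, groups, group1 = "A")

  design <- cbind(1, groups == "A")
  lf <- limma::eBayes(limma::lmFit(norm, design))
  expect_equal(fit$log2FC, unname(lf$coefficients[, 2]), tolerance = 1e-8)
  expect_gt(cor(fit$t, lf$t[, 2]), 0.999)
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 0.2 * max(1, lf$df.prior))
})

test_that("null p-values from the moderated fit are calibrated", {
  norm <- toy_matrix(2000, 20, seed = 12)
  fit <- fit_moderated_de(norm, rep(c("A", "B"), each = 10), group1 = "A")
  frac <- mean(fit$p < 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("constant genes are testable whenever the prior has weight", {
  norm <- toy_matrix(60, 8, seed = 5)
  norm[1, ] <- 3  # zero residual variance
  fit <- fit_moderated_de(norm, rep(c("A", "B"), each = 4), group1 = "A")
  expect_true(is.finite(fit$t[1]))
  expect_identical(fit$log2FC[1], 0)
  expect_error(fit_moderated_de(norm, c("A", rep("B", 7))), "at least 2 samples")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.1, NaN)), "NA")

  withr::with_seed(21, {
    for (rep in 1:20) {
      p <- runif(sample(5:200, 1))
      adj <- adjust_bh(p)
      expect_equal(adj, oracle_bh(p))
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in rank
    }
  })
})

test_that("DEG calling applies strict fold-change and adjusted-p thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2FC = c(1.2, 1.2, -1.5, 1.0),
                    p_adj = c(0.01, 0.2, 0.001, 0.01))
  got <- call_degs(tab)
  expect_identical(got$up, "a")        # lfc 1.2, padj 0.01
  expect_identical(got$down, "c")      # lfc -1.5, padj 0.001
  expect_false("b" %in% unlist(got))   # padj 0.2 -> ns
  expect_false("d" %in% unlist(got))   # lfc exactly at the cut -> strict
})

test_that("pairwise sweep finds a planted marker and validates its labels", {
  cfg <- tiny_config(n_markers = 1L, n_leaky = 0L, n_stromal = 0L,
                     marker_fold = 16, dispersion = 0.05)
  im <- generate_sorted_immune(cfg)
  norm <- to_log_cpm(im$counts)
  up <- pairwise_nk_degs(norm, im$annotation$cell_type)
  expect_setequal(names(up), c("T", "B"))
  marker <- im$truth$planted_nk_markers
  expect_true(all(vapply(up, function(s) marker %in% s, logical(1))))

  expect_error(pairwise_nk_degs(norm, rep("NK", ncol(norm))), "non-target")
  expect_error(pairwise_nk_degs(norm, im$annotation$cell_type, target = "Missing"),
               "not found")
})
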