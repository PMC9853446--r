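test_that("all generators are deterministic given the configuration seed", {
  cfg <- tiny_config()
  expect_identical(generate_sorted_immune(cfg), generate_sorted_immune(cfg))
  expect_identical(generate_cell_lines(cfg, character(0)),
                   generate_cell_lines(cfg, character(0)))
  expect_identical(generate_compartments(cfg, character(0)),
                   generate_compartments(cfg, character(0)))
  expect_identical(generate_single_cell(cfg), generate_single_cell(cfg))
  expect_identical(generate_survival_cohort(rep(c("high", "low"), 10), 0.5, seed = 3),
                   generate_survival_cohort(rep(c("high", "low"), 10), 0.5, seed = 3))
  cfg2 <- tiny_config(seed = 43L)
  expect_false(identical(generate_sorted_immune(cfg2)$counts,
                         generate_sorted_immune(cfg)$counts))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_sorted_immune(tiny_config())); after <- runif(1)
  expect_identical(before, after)
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_config(n_markers = 300L), "smaller than n_genes")
  expect_error(tiny_config(marker_fold = 1), "exceed 1")
  expect_error(tiny_config(n_replicates = 1L), "at least 2 replicates")
  expect_error(tiny_config(cell_types = c("T", "B")), "include 'NK'")
  expect_error(tiny_config(dropout_rate = 1.2), "\\[0, 1\\]")
  expect_error(tiny_config(n_leaky = 9L, n_stromal = 9L), "fit within")
})

test_that("sorted-immune panel plants markers at the configured fold", {
  cfg <- tiny_config(n_genes = 1000L, n_markers = 20L, n_leaky = 0L,
                     n_stromal = 0L, dispersion = 1e-4)
  im <- generate_sorted_immune(cfg)
  expect_identical(ncol(im$counts), nrow(im$annotation))
  is_nk <- im$annotation$cell_type == "NK"
  ratio <- rowMeans(im$counts[im$truth$planted_nk_markers, is_nk]) /
    rowMeans(im$counts[im$truth$planted_nk_markers, !is_nk])
  gm <- exp(mean(log(ratio)))
  expect_gt(gm, 8 * 0.8)
  expect_lt(gm, 8 * 1.2)

  empty <- generate_sorted_immune(tiny_config(n_markers = 0L, n_leaky = 0L,
                                              n_stromal = 0L))
  expect_length(empty$truth$planted_nk_markers, 0L)
})

test_that("cell-line panels express leaky genes and silence other markers", {
  cfg <- tiny_config(dispersion = 0.01)
  truth <- generate_sorted_immune(cfg)$truth
  leaky <- truth$planted_leaky_genes[1]
  lines <- generate_cell_lines(cfg, leaky)
  im <- generate_sorted_immune(cfg)
  nk_norm <- to_log_cpm(im$counts)[, im$annotation$cell_type == "NK"]

  fail <- tumour_line_filter(nk_norm, to_log_cpm(lines),
                             genes = truth$planted_nk_markers)
  expect_identical(as.character(fail), leaky)  # only the leaky gene has higher line median

  none <- generate_cell_lines(cfg, character(0))
  fail0 <- tumour_line_filter(nk_norm, to_log_cpm(none),
                              genes = truth$planted_nk_markers)
  expect_length(fail0, 0L)  # all planted markers below the NK median

  expect_error(generate_cell_lines(cfg, "NOT_A_GENE"), "unknown gene")
})

test_that("compartment quadruplets plant stromal contamination per patient", {
  cfg <- tiny_config(dispersion = 0.01)
  truth <- generate_sorted_immune(cfg)$truth
  comps <- generate_compartments(cfg, truth$planted_stromal_genes)
  ann <- comps$annotation
  norm <- cpm(comps$counts)
  for (g in truth$planted_stromal_genes) {
    ratios <- vapply(unique(ann$patient), function(p) {
      fap <- norm[g, ann$patient == p & ann$compartment == "FAP"]
      leu <- norm[g, ann$patient == p & ann$compartment == "CD45"]
      fap / leu
    }, numeric(1))
    expect_gte(mean(ratios > 1), 0.9)
  }

  clean <- generate_compartments(cfg, character(0))
  fail <- stromal_filter(cpm(clean$counts), clean$annotation$compartment,
                         clean$annotation$patient,
                         genes = truth$planted_nk_markers)
  expect_length(fail, 0L)  # nothing planted, nothing removed

  expect_error(generate_compartments(cfg, character(0), n_patients = 2L),
               "at least 3")
})

test_that("single-cell generator mirrors bulk structure with dropout", {
  all_zero <- generate_single_cell(tiny_config(dropout_rate = 1))
  expect_identical(Matrix::nnzero(all_zero$counts), 0L)
  expect_identical(length(all_zero$labels), ncol(all_zero$counts))

  cfg <- tiny_config(dropout_rate = 0, n_cells_per_type = 150L, dispersion = 0.05)
  sc <- generate_single_cell(cfg)
  im <- generate_sorted_immune(cfg)
  markers <- im$truth$planted_nk_markers
  ratio_sc <- rowMeans(as.matrix(sc$counts[markers, sc$labels == "NK"])) /
    rowMeans(as.matrix(sc$counts[markers, sc$labels != "NK"]))
  ratio_bulk <- rowMeans(im$counts[markers, im$annotation$cell_type == "NK"]) /
    rowMeans(im$counts[markers, im$annotation$cell_type != "NK"])
  expect_lt(abs(exp(mean(log(ratio_sc))) / exp(mean(log(ratio_bulk))) - 1), 0.1)
})

test_that("bulk mixtures interpolate between background and NK profiles", {
  cfg <- tiny_config(dispersion = 0)  # deterministic expected-value mode
  im <- generate_sorted_immune(cfg)
  ref <- mixture_reference(im)
  mix <- generate_bulk_mixtures(ref$nk, ref$background, c(0, 0.5, 1), cfg)
  got <- cpm(mix$counts)
  expect_equal(got[, 1], 1e6 * ref$background / sum(ref$background),
               tolerance = 1e-10)
  expect_equal(got[, 3], 1e6 * ref$nk / sum(ref$nk), tolerance = 1e-10)

  fr <- seq(0, 0.3, length.out = 10)
  mono <- generate_bulk_mixtures(ref$nk, ref$background, fr, cfg)
  marker <- im$truth$planted_nk_markers[1]
  expect_equal(cor(cpm(mono$counts)[marker, ], fr, method = "spearman"), 1)

  expect_error(generate_bulk_mixtures(ref$nk, ref$background, c(0.2, 1.4), cfg),
               "\\[0, 1\\]")
})

test_that("survival cohorts respect censoring and record covariates", {
  rec <- generate_survival_cohort(rep(c("high", "low"), each = 30), 0.7,
                                  censoring_rate = 0, seed = 8)
  expect_true(all(rec$event == 1L))
  expect_setequal(names(rec), c("sample", "time", "event", "group", "age",
                                "stage", "mmr"))
  expect_true(all(rec$stage %in% 1:3) && all(rec$mmr %in% 0:1))

  # numeric scores are median-split into groups
  rec2 <- generate_survival_cohort(runif(50), 0.5, seed = 9)
  expect_setequal(unique(rec2$group), c("high", "low"))
  expect_error(generate_survival_cohort(rep("high", 10), 0, censoring_rate = 1),
               "censoring_rate")
})
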