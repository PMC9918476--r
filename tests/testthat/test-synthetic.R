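test_that("the generator is deterministic and conserves purity + weights", {
  co1 <- generate_cohort(small_sim_config(seed = 11))
  co2 <- generate_cohort(small_sim_config(seed = 11))
  expect_identical(co1$dataset$values, co2$dataset$values)
  expect_identical(co1$truth$samples, co2$truth$samples)

  tr <- co1$truth$samples
  total <- tr$purity + tr$w_acinar + tr$w_immune + tr$w_caf + tr$w_background
  expect_true(all(abs(total - 1) < 1e-12))
  expect_true(all(tr$purity >= 0 & tr$purity <= 1))
  expect_true(all(tr[, c("w_acinar", "w_immune", "w_caf", "w_background")] >= 0))
})

test_that("adding samples of later tissue types never perturbs earlier ones", {
  a <- generate_cohort(small_sim_config(seed = 5))
  b <- generate_cohort(small_sim_config(seed = 5, n_acc = 8, n_normal_other = 9))
  shared <- intersect(colnames(a$dataset$values), colnames(b$dataset$values))
  expect_identical(a$dataset$values[, shared], b$dataset$values[, shared])
})

test_that("pure samples carry no contamination signal (noise-free mixture identity)", {
  cfg <- small_sim_config(seed = 2, noise_sd = 0)
  co <- generate_cohort(cfg)
  tr <- co$truth$samples
  blocks <- co$truth$gene_blocks
  base <- 2^cfg$baseline_log2

  # cell lines have p = 1: acinar/immune/caf genes sit exactly at baseline
  cl <- tr$sample_id[tr$tissue_type == "cell_line"]
  for (blk in c("acinar", "immune", "caf")) {
    vals <- co$dataset$values[names(blocks)[blocks == blk], cl]
    expect_true(all(abs(vals - log2(base + 1)) < 1e-12))
  }
})

test_that("a primary's acinar-block values equal the closed-form mixture", {
  cfg <- small_sim_config(seed = 9, noise_sd = 0)
  co <- generate_cohort(cfg)
  tr <- co$truth$samples
  blocks <- co$truth$gene_blocks
  base <- 2^cfg$baseline_log2
  prim <- tr[tr$tissue_type == "primary_tumor", ][1:5, ]
  acn <- names(blocks)[blocks == "acinar"]
  for (r in seq_len(nrow(prim))) {
    # tumor contributes baseline, the acinar compartment elevated baseline
    lin <- prim$purity[r] * base +
      prim$w_acinar[r] * base * 2^cfg$delta +
      (prim$w_immune[r] + prim$w_caf[r]) * base
    expect_equal(unname(co$dataset$values[acn, prim$sample_id[r]]),
                 rep(log2(lin + 1), length(acn)), tolerance = 1e-12)
  }
})

test_that("paired cell lines and metastases share subtype and pair structure", {
  co <- generate_cohort(small_sim_config(seed = 4))
  tr <- co$truth$samples
  pairs <- split(tr, tr$pair_id)
  expect_true(length(pairs) >= 3)
  for (grp in pairs) {
    expect_equal(nrow(grp), 2)
    expect_true("primary_tumor" %in% grp$tissue_type)
    expect_length(unique(grp$subtype), 1)
    expect_length(unique(grp$strength), 1)
  }
})

test_that("simulated gene sets encode the designed block structure", {
  cfg <- small_sim_config(seed = 1)
  co <- generate_cohort(cfg)
  blocks <- co$truth$gene_blocks
  sets <- co$gene_sets
  expect_true(all(blocks[sets[["sim_basal"]]$genes] == "tumor_basal"))
  adex_blocks <- blocks[sets[["sim_ADEX-like"]]$genes]
  expect_setequal(unique(adex_blocks), c("acinar", "background"))
  imm_blocks <- blocks[sets[["sim_immunogenic"]]$genes]
  frac_classical <- mean(imm_blocks == "tumor_classical")
  expect_gt(frac_classical, 0.10)
  expect_lt(frac_classical, 0.16)
  expect_true(all(blocks[sets[["sim_housekeeping"]]$genes] == "background"))
  # ADEX-like background genes and housekeeping genes do not overlap
  expect_length(intersect(sets[["sim_ADEX-like"]]$genes,
                          sets[["sim_housekeeping"]]$genes), 0)
})

test_that("expected score slopes have the mixture-model signs", {
  cfg <- simulation_config(seed = 1)
  expect_gt(expected_score_slope(cfg, "tumor_shared"), 0)
  expect_lt(expected_score_slope(cfg, "acinar"), 0)
  expect_lt(expected_score_slope(cfg, "immune"), 0)
  expect_lt(expected_score_slope(cfg, "caf"), 0)
  expect_equal(expected_score_slope(cfg, "background"), 0)
  expect_error(expected_score_slope(cfg, "nonesuch"), "unknown block")
})

test_that("the analytic slope matches a large-cohort Monte-Carlo slope", {
  cfg <- simulation_config(seed = 21, n_primary = 10000, n_cell_line = 0,
                           n_pdx = 0, n_caf = 0, n_normal_pancreas = 0,
                           n_acc = 0, n_metastasis = 0, n_normal_other = 0)
  co <- generate_cohort(cfg)
  tr <- co$truth$samples
  blocks <- co$truth$gene_blocks
  for (blk in c("acinar", "tumor_shared")) {
    score <- colMeans(co$dataset$values[names(blocks)[blocks == blk], ])
    fit <- stats::lm(score ~ tr$purity)
    mc_slope <- stats::coef(fit)[2]
    mc_se <- summary(fit)$coefficients[2, 2]
    expect_lt(abs(expected_score_slope(cfg, blk) - mc_slope), 3 * mc_se)
  }
})

test_that("write_cohort emits a consumable trio plus truth JSON", {
  co <- generate_cohort(small_sim_config(seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  ds <- read_expression(paths[["expression"]], scale = "log2",
                        pseudocount = 1,
                        metadata = read_metadata(paths[["metadata"]]))
  expect_identical(ds$values, co$dataset$values)
  expect_identical(ds$metadata$tissue_type, co$dataset$metadata$tissue_type)
  sets <- read_gmt(paths[["gene_sets"]])
  expect_identical(names(sets), names(co$gene_sets))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$samples$purity, co$truth$samples$purity)
})
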