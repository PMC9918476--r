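two_clouds <- function(n_per = 6, sep = 50, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 3), ncol = 3),
             matrix(rnorm(n_per * 3, mean = sep), ncol = 3))
  rownames(x) <- paste0("it", seq_len(2 * n_per))
  x
}

test_that("k = 1 gives an all-ones consensus matrix and one cluster", {
  x <- two_clouds()
  cc <- consensus_cluster(x, k = 1, resamples = 10, seed = 1)
  expect_true(all(cc$M[cc$N > 0] == 1))
  expect_true(all(cc$assignments == 1L))
})

test_that("well-separated clouds give a 0/1 consensus matrix and the true partition", {
  x <- two_clouds(n_per = 6, sep = 50)
  cc <- consensus_cluster(x, k = 2, resamples = 100, seed = 7)
  truth <- rep(1:2, each = 6)
  within <- outer(truth, truth, "==")
  expect_true(all(cc$M[within & cc$N > 0] == 1))
  expect_true(all(cc$M[!within & cc$N > 0] == 0))
  expect_equal(rand_index(cc$assignments, truth), 1)
})

test_that("consensus matrices are symmetric, bounded, and seeded-reproducible", {
  set.seed(20)
  x <- matrix(rnorm(30 * 4), ncol = 4,
              dimnames = list(paste0("it", 1:30), NULL))
  cc <- consensus_cluster(x, k = 3, resamples = 30, seed = 3)
  expect_lt(max(abs(cc$M - t(cc$M))), 1e-12)
  expect_true(all(cc$M >= 0 & cc$M <= 1))
  expect_true(all(diag(cc$M) == 1))
  cc2 <- consensus_cluster(x, k = 3, resamples = 30, seed = 3)
  expect_identical(cc$M, cc2$M)
  expect_identical(cc$assignments, cc2$assignments)
})

test_that("the consensus matrix equals an independent naive replay", {
  set.seed(21)
  x <- matrix(rnorm(8 * 3), ncol = 3, dimnames = list(paste0("it", 1:8), NULL))
  cc <- consensus_cluster(x, k = 2, resamples = 20, subsample_fraction = 0.8,
                          seed = 5)
  M_ref <- naive_consensus_replay(x, k = 2, resamples = 20,
                                  subsample_fraction = 0.8, seed = 5)
  expect_identical(unname(cc$M), M_ref)
})

test_that("more resamples concentrate the consensus matrix", {
  set.seed(22)
  x <- rbind(matrix(rnorm(20 * 3), ncol = 3),
             matrix(rnorm(20 * 3, mean = 1.6), ncol = 3))
  rownames(x) <- paste0("it", 1:40)
  ref <- consensus_cluster(x, k = 2, resamples = 400, seed = 100)$M
  err <- function(R, seeds) {
    mean(vapply(seeds, function(s) {
      max(abs(consensus_cluster(x, k = 2, resamples = R, seed = s)$M - ref))
    }, numeric(1)))
  }
  expect_gt(err(25, 1:3), err(150, 1:3))
})

test_that("duplicated items always co-cluster with consensus 1", {
  set.seed(23)
  base <- matrix(rnorm(6 * 4), ncol = 4)
  x <- rbind(base, base[1, , drop = FALSE]) # item 7 duplicates item 1
  rownames(x) <- paste0("it", 1:7)
  cc <- consensus_cluster(x, k = 2, resamples = 50, seed = 2)
  expect_equal(cc$M["it1", "it7"], 1)
  expect_equal(cc$assignments[["it1"]], cc$assignments[["it7"]])
})

test_that("degenerate k choices behave as forced", {
  x <- two_clouds(n_per = 3)
  cc <- consensus_cluster(x, k = nrow(x), resamples = 10,
                          subsample_fraction = 1, seed = 1)
  expect_equal(sort(unname(cc$assignments)), seq_len(nrow(x)))
  expect_error(consensus_cluster(x, k = nrow(x) + 1, resamples = 5, seed = 1),
               "k")
})

test_that("assign_subtypes recovers ground-truth subtypes on a clean cohort", {
  cfg <- small_sim_config(seed = 31, delta = 2, noise_sd = 0.3,
                          n_primary = 100)
  co <- generate_cohort(cfg)
  prim <- filter_samples(co$dataset, list(tissue_type = "primary_tumor"),
                         verbose = FALSE)
  col <- co$gene_sets[c("sim_basal", "sim_classical")]
  asg <- assign_subtypes(prim, col, resamples = 100, seed = 1)
  truth <- co$truth$samples
  want <- paste0("sim_", truth$subtype[match(names(asg$labels),
                                             truth$sample_id)])
  expect_gte(mean(asg$labels == want), 0.95)
})

test_that("a single-set collection yields one label for everyone", {
  co <- generate_cohort(small_sim_config(seed = 32))
  asg <- assign_subtypes(co$dataset, co$gene_sets["sim_basal"],
                         resamples = 10, seed = 1)
  expect_true(all(asg$labels == "sim_basal"))
})

test_that("subtype labels are invariant to collection order", {
  cfg <- small_sim_config(seed = 33, delta = 2, noise_sd = 0.3)
  co <- generate_cohort(cfg)
  prim <- filter_samples(co$dataset, list(tissue_type = "primary_tumor"),
                         verbose = FALSE)
  a <- assign_subtypes(prim, co$gene_sets[c("sim_basal", "sim_classical")],
                       resamples = 60, seed = 9)
  b <- assign_subtypes(prim, co$gene_sets[c("sim_classical", "sim_basal")],
                       resamples = 60, seed = 9)
  expect_identical(a$labels, b$labels)
})

test_that("samples copied from k prototypes are recovered exactly", {
  set.seed(34)
  protos <- matrix(rnorm(3 * 25, sd = 4), nrow = 3)
  reps <- rep(1:3, each = 6)
  vals <- t(protos[reps, , drop = FALSE])
  dimnames(vals) <- list(paste0("g", 1:25), paste0("s", 1:18))
  cc <- consensus_cluster(t(vals), k = 3, resamples = 50, seed = 4)
  expect_equal(rand_index(cc$assignments, reps), 1)
})

test_that("decompose_signature separates the mixed ADEX-like list", {
  co <- generate_cohort(simulation_config(seed = 35))
  adex <- co$gene_sets[["sim_ADEX-like"]]
  dec <- decompose_signature(co$dataset, adex, k = 2, resamples = 100,
                             seed = 1)
  blocks <- co$truth$gene_blocks[names(dec$clusters)]
  expect_gte(rand_index(dec$clusters, as.integer(factor(blocks))), 0.95)
  # the acinar cluster is the one elevated in normal pancreas and ACC
  acinar_cl <- dec$clusters[[which(blocks == "acinar")[1]]]
  prof <- dec$tissue_profile
  expect_gt(prof[acinar_cl, "normal_pancreas"], prof[acinar_cl, "cell_line"])
  expect_gt(prof[acinar_cl, "acc"], prof[acinar_cl, "cell_line"])
})

test_that("k equal to the number of genes gives singleton gene clusters", {
  co <- generate_cohort(small_sim_config(seed = 36))
  tiny <- gene_set("tiny", co$gene_sets[["sim_basal"]]$genes[1:4])
  dec <- decompose_signature(co$dataset, tiny, k = 4, resamples = 10,
                             subsample_fraction = 1, seed = 1)
  expect_equal(sort(unname(dec$clusters)), 1:4)
})

test_that("consensus results serialize to readable TSV/JSON", {
  x <- two_clouds(n_per = 3)
  cc <- consensus_cluster(x, k = 2, resamples = 20, seed = 1)
  prefix <- file.path(withr::local_tempdir(), "cc")
  paths <- write_consensus(cc, prefix)
  expect_true(all(file.exists(paths)))
  m <- utils::read.table(paths[["consensus"]], sep = "\t", header = TRUE,
                         row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(m), cc$M)
  params <- jsonlite::read_json(paths[["params"]], simplifyVector = TRUE)
  expect_equal(params$resamples, 20)
})
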