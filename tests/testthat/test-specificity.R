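# One mid-size cohort reused across the specificity tests.
spec_cohort <- generate_cohort(small_sim_config(seed = 41, n_primary = 100))

spec_score <- function(set_name) {
  gene_set_score(spec_cohort$dataset, spec_cohort$gene_sets[[set_name]],
                 verbose = FALSE)
}

spec_primaries <- local({
  md <- spec_cohort$dataset$metadata
  md$sample_id[md$tissue_type == "primary_tumor"]
})

test_that("purity correlation recovers the mixture-model signs", {
  md <- spec_cohort$dataset$metadata
  acn <- spec_score("sim_ADEX-like")
  res <- purity_correlation(acn[names(acn) %in% spec_primaries], md)
  expect_lt(res$rho, 0)
  expect_lt(res$p, 0.01)
  expect_equal(res$n_used, length(spec_primaries))

  shared <- spec_score("sim_tumor_shared")
  res2 <- purity_correlation(shared[names(shared) %in% spec_primaries], md)
  expect_gt(res2$rho, 0)

  md_none <- md
  md_none$purity <- NA_real_
  expect_error(purity_correlation(acn, md_none), ">= 3")
})

test_that("compartment contrasts separate contamination from tumor blocks", {
  tab <- score_panel(spec_cohort$dataset, spec_cohort$gene_sets,
                     verbose = FALSE)
  md <- spec_cohort$dataset$metadata
  panel <- compartment_panel(tab, md, list(c("primary_tumor", "cell_line"),
                                           c("primary_tumor", "caf")))
  adex_cl <- panel[panel$gene_set == "sim_ADEX-like" &
                     panel$group_b == "cell_line", ]
  expect_gt(adex_cl$mean_a, adex_cl$mean_b)
  expect_lt(adex_cl$p, 0.01)

  basal_cl <- panel[panel$gene_set == "sim_basal" &
                      panel$group_b == "cell_line", ]
  expect_gte(basal_cl$mean_b, basal_cl$mean_a)

  basal_caf <- panel[panel$gene_set == "sim_basal" &
                       panel$group_b == "caf", ]
  expect_gt(basal_caf$mean_a, basal_caf$mean_b)

  expect_match(attr(panel, "standardization_cohort"), "all_scored_samples")
  expect_error(compartment_panel(tab, md, list(c("primary_tumor", "organoid"))),
               "unknown tissue_type")
})

test_that("a group contrasted against itself is a null result", {
  tab <- score_panel(spec_cohort$dataset,
                     spec_cohort$gene_sets["sim_basal"], verbose = FALSE)
  md <- spec_cohort$dataset$metadata
  panel <- compartment_panel(tab, md, list(c("caf", "caf")))
  expect_equal(panel$p, 1)
  expect_equal(panel$mean_a, panel$mean_b)
})

test_that("paired retention holds for tumor blocks and breaks for acinar", {
  md <- spec_cohort$dataset$metadata
  basal <- paired_retention(spec_score("sim_basal"), md)
  expect_gte(basal$rho, 0.7)
  expect_gte(basal$loss, -0.1)

  adex <- paired_retention(spec_score("sim_ADEX-like"), md)
  expect_lt(adex$loss, 0)
  expect_lt(abs(adex$rho), abs(basal$rho))
})

test_that("paired retention handles identity, few pairs and duplicated roles", {
  md <- data.frame(sample_id = c("p1", "c1", "p2", "c2", "p3", "c3"),
                   tissue_type = rep(c("primary_tumor", "cell_line"), 3),
                   pair_id = rep(c("A", "B", "C"), each = 2),
                   stringsAsFactors = FALSE)
  sc <- stats::setNames(c(1, 1, 5, 5, 9, 9), md$sample_id)
  res <- paired_retention(sc, md)
  expect_equal(res$rho, 1)
  expect_equal(res$loss, 0)

  md_dup <- rbind(md, data.frame(sample_id = "c1b",
                                 tissue_type = "cell_line", pair_id = "A"))
  sc_dup <- c(sc, c1b = 2)
  expect_error(paired_retention(sc_dup, md_dup), "pair 'A'")

  expect_error(paired_retention(sc[1:4], md[1:4, ]), ">= 3")
})

test_that("gene list overlap is asymmetric set arithmetic", {
  a <- gene_set("a", paste0("g", 1:8))
  expect_equal(gene_list_overlap(a, a)$fraction_of_a, 1)
  expect_equal(gene_list_overlap(a, gene_set("d", "zz"))$count, 0)
  b <- gene_set("b", c("g1", "g5", "x1", "x2"))
  res <- gene_list_overlap(a, b)
  expect_equal(res$count, 2)
  expect_equal(res$fraction_of_a, 0.25)
  expect_equal(gene_list_overlap(b, a)$fraction_of_a, 0.5)
})

test_that("label concordance maps vocabularies and matches binomial chance", {
  ids <- paste0("s", 1:4)
  la <- stats::setNames(c("basal", "basal", "classical", "classical"), ids)
  lb <- stats::setNames(c("sq", "sq", "prog", "prog"), ids)
  expect_equal(label_concordance(la, la)$concordance, 1)
  expect_equal(label_concordance(la, lb)$concordance, 1)
  lb2 <- lb
  lb2[4] <- "sq"
  expect_equal(label_concordance(la, lb2)$concordance, 0.75)

  set.seed(50)
  ids <- paste0("s", 1:1000)
  ra <- stats::setNames(sample(c("A", "B"), 1000, replace = TRUE), ids)
  rb <- stats::setNames(sample(c("X", "Y"), 1000, replace = TRUE), ids)
  conc <- label_concordance(ra, rb)$concordance
  expect_gte(conc, 0.5)
  expect_lt(abs(conc - 0.5), 0.05)

  expect_error(label_concordance(la, lb[1:3]), "different sample ids")
})

test_that("verdict rules operationalize the specificity evidence", {
  non_tumor_frag <- list(purity_rho = -0.45, purity_p = 1e-6,
                         contrast = list(mean_primary = 0.5,
                                         mean_derived = -0.6, p = 1e-4),
                         paired_loss = -1.1)
  v <- signature_verdict(non_tumor_frag)
  expect_equal(v$verdict, "non_tumor")
  expect_true("purity_confounded" %in% v$rules_fired)

  intrinsic_frag <- list(purity_rho = 0.2, purity_p = 0.01,
                         contrast = list(mean_primary = 0.1,
                                         mean_derived = 0.4, p = 0.2),
                         paired_loss = 0.3)
  expect_equal(signature_verdict(intrinsic_frag)$verdict, "tumor_intrinsic")

  empty <- signature_verdict(list())
  expect_equal(empty$verdict, "ambiguous")
  expect_equal(empty$rules_fired, "insufficient_evidence")

  # determinism: same fragment, same verdict
  expect_identical(signature_verdict(non_tumor_frag),
                   signature_verdict(non_tumor_frag))

  # thresholds are configuration and are echoed
  lax <- verdict_rules(rho_threshold = -0.5, p_threshold = 0.05)
  v2 <- signature_verdict(list(purity_rho = -0.3, purity_p = 1e-4,
                               contrast = list(mean_primary = 0,
                                               mean_derived = 0.2, p = 0.5)),
                          lax)
  expect_equal(v2$verdict, "tumor_intrinsic")
  expect_equal(v2$rules$rho_threshold, -0.5)
})

test_that("synthetic fragments produce the designed verdicts", {
  md <- spec_cohort$dataset$metadata
  frag_for <- function(set_name) {
    sv <- spec_score(set_name)
    pc <- purity_correlation(sv[names(sv) %in% spec_primaries], md)
    z <- standardize_scores(sv)
    tt <- md$tissue_type
    ts <- rank_sum_test(z[tt == "primary_tumor"], z[tt == "cell_line"])
    rt <- paired_retention(sv, md)
    list(purity_rho = pc$rho, purity_p = pc$p,
         contrast = list(mean_primary = mean(z[tt == "primary_tumor"]),
                         mean_derived = mean(z[tt == "cell_line"]),
                         p = ts$p),
         paired_loss = rt$loss)
  }
  expect_equal(signature_verdict(frag_for("sim_ADEX-like"))$verdict,
               "non_tumor")
  expect_equal(signature_verdict(frag_for("sim_basal"))$verdict,
               "tumor_intrinsic")
})

test_that("robustness panel exposes compartment-driven spread", {
  panel <- signature_robustness_panel(spec_cohort$gene_sets,
                                      spec_cohort$dataset)
  hk <- panel[panel$gene_set == "sim_housekeeping", ]
  acn <- panel[panel$gene_set == "sim_ADEX-like", ]
  # housekeeping has no compartment signal: its spread is the smallest and
  # sits at the group-mean noise floor, far below any compartment set
  expect_equal(hk$spread, min(panel$spread))
  expect_lt(hk$spread, acn$spread / 2)
  expect_gt(acn$spread, 1)
  # the acinar spread is driven by acinar-rich tissues
  tissue_means <- acn[, grep("^mean\\.", names(acn))]
  top <- names(tissue_means)[which.max(as.numeric(tissue_means))]
  expect_true(top %in% c("mean.normal_pancreas", "mean.acc"))

  # spread is invariant to sample order
  perm <- sample(ncol(spec_cohort$dataset$values))
  ds_perm <- expression_dataset(spec_cohort$dataset$values[, perm],
                                scale = "log2", pseudocount = 1,
                                metadata = spec_cohort$dataset$metadata[perm, ])
  panel2 <- signature_robustness_panel(spec_cohort$gene_sets, ds_perm)
  expect_equal(panel2$spread, panel$spread)
})
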