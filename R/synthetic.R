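#' Simulation configuration for synthetic bulk-tumor cohorts
#'
#' The generator emulates the statistical structure that purity-confounding
#' analyses of bulk pancreatic tumors rely on: each bulk sample is a
#' purity-weighted linear mixture of compartment expression profiles (two
#' tumor subtypes sharing a common tumor block, acinar, immune and fibroblast
#' compartments, plus a flat housekeeping background), observed on the log2
#' scale with additive Gaussian noise.
#'
#' @param n_primary,n_cell_line,n_pdx,n_caf,n_normal_pancreas,n_acc,n_metastasis,n_normal_other
#'   Sample counts per tissue type.
#' @param purity_alpha,purity_beta Beta shape parameters for primary-tumor
#'   (and metastasis) neoplastic purity. The default Beta(5, 3) is
#'   right-shifted, mimicking resected-tumor cellularity ranges.
#' @param acc_purity_alpha,acc_purity_beta Beta shapes for acinar cell
#'   carcinoma purity (high by default: these are high-purity non-PDAC
#'   tumors).
#' @param subtype_fraction_basal Probability that a tumor is basal-like.
#' @param block_sizes Named integer vector of genes per compartment block.
#' @param delta Elevation effect size in log2 units: an elevated gene's mean
#'   is `baseline_log2 + delta` in its compartment.
#' @param tumor_strength_sdlog Log-normal sdlog of the per-tumor signature
#'   activation strength multiplying the tumor-block elevation; inherited by
#'   derived cell lines and metastases (it is tumor-intrinsic), producing the
#'   range of signature expression seen across real primaries.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param baseline_log2 Background log2 expression level (linear baseline is
#'   `2^baseline_log2`).
#' @param paired_fraction Fraction of cell lines / metastases paired to a
#'   distinct primary (sharing subtype and strength via a `pair_id`).
#' @param contamination_alpha Dirichlet concentration over the
#'   (acinar, immune, caf) contamination split of primaries and ACCs.
#' @param pdx_caf_weight Small residual stromal weight in PDXs.
#' @param normal_pancreas_weights Compartment weights of normal pancreas
#'   (acinar-dominated).
#' @param immunogenic_classical_fraction Fraction of the simulated
#'   immunogenic list drawn from the tumor-classical block, emulating the
#'   tumor-gene contamination of published immunogenic lists.
#' @param adex_background_genes Number of nonspecific background genes mixed
#'   into the simulated ADEX-like list.
#' @param housekeeping_set_size Size of the housekeeping control set.
#' @param seed Master seed; each sample draws from a deterministic,
#'   counter-based substream so adding samples of one tissue type never
#'   perturbs samples already generated.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_primary = 150, n_cell_line = 25, n_pdx = 15,
                              n_caf = 10, n_normal_pancreas = 15, n_acc = 6,
                              n_metastasis = 25, n_normal_other = 10,
                              purity_alpha = 5, purity_beta = 3,
                              acc_purity_alpha = 9, acc_purity_beta = 1,
                              subtype_fraction_basal = 0.5,
                              block_sizes = c(tumor_shared = 40,
                                              tumor_basal = 40,
                                              tumor_classical = 40,
                                              acinar = 40, immune = 40,
                                              caf = 40, background = 200),
                              delta = 1.5, tumor_strength_sdlog = 0.2,
                              noise_sd = 0.4, baseline_log2 = 3,
                              paired_fraction = 1,
                              contamination_alpha = c(acinar = 2, immune = 2,
                                                      caf = 3),
                              pdx_caf_weight = 0.05,
                              normal_pancreas_weights = c(acinar = 0.85,
                                                          immune = 0.10,
                                                          caf = 0.05),
                              immunogenic_classical_fraction = 0.13,
                              adex_background_genes = 20,
                              housekeeping_set_size = 40,
                              seed = 1) {
  cfg <- list(n_primary = n_primary, n_cell_line = n_cell_line, n_pdx = n_pdx,
              n_caf = n_caf, n_normal_pancreas = n_normal_pancreas,
              n_acc = n_acc, n_metastasis = n_metastasis,
              n_normal_other = n_normal_other,
              purity_alpha = purity_alpha, purity_beta = purity_beta,
              acc_purity_alpha = acc_purity_alpha,
              acc_purity_beta = acc_purity_beta,
              subtype_fraction_basal = subtype_fraction_basal,
              block_sizes = block_sizes, delta = delta,
              tumor_strength_sdlog = tumor_strength_sdlog,
              noise_sd = noise_sd, baseline_log2 = baseline_log2,
              paired_fraction = paired_fraction,
              contamination_alpha = contamination_alpha,
              pdx_caf_weight = pdx_caf_weight,
              normal_pancreas_weights = normal_pancreas_weights,
              immunogenic_classical_fraction = immunogenic_classical_fraction,
              adex_background_genes = adex_background_genes,
              housekeeping_set_size = housekeeping_set_size,
              seed = seed)
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  .assert(all(counts >= 0), "sample counts must be >= 0")
  .assert(delta > 0, "delta must be > 0")
  .assert(noise_sd >= 0, "noise_sd must be >= 0")
  .assert(paired_fraction >= 0 && paired_fraction <= 1,
          "paired_fraction must be in [0, 1]")
  .assert(subtype_fraction_basal >= 0 && subtype_fraction_basal <= 1,
          "subtype_fraction_basal must be in [0, 1]")
  need <- c("tumor_shared", "tumor_basal", "tumor_classical", "acinar",
            "immune", "caf", "background")
  .assert(all(need %in% names(block_sizes)) && all(block_sizes[need] > 0),
          "block_sizes must name positive sizes for: ",
          paste(need, collapse = ", "))
  .assert(block_sizes[["background"]] >=
            adex_background_genes + housekeeping_set_size,
          "background block too small for the ADEX-like and housekeeping sets")
  structure(cfg, class = "simulation_config")
}

# Block label per gene and gene ids, in fixed block order.
.block_prefix <- c(tumor_shared = "TSH", tumor_basal = "TBS",
                   tumor_classical = "TCL", acinar = "ACN", immune = "IMN",
                   caf = "CAF", background = "BGR")

.gene_blocks <- function(config) {
  sizes <- config$block_sizes[names(.block_prefix)]
  blocks <- rep(names(sizes), times = sizes)
  ids <- unlist(lapply(names(sizes), function(b) {
    sprintf("%s%03d", .block_prefix[[b]], seq_len(sizes[[b]]))
  }), use.names = FALSE)
  names(blocks) <- ids
  blocks
}

# Which gene blocks each compartment profile elevates.
.profile_elevates <- list(
  tumor_basal = c("tumor_basal", "tumor_shared"),
  tumor_classical = c("tumor_classical", "tumor_shared"),
  acinar = "acinar",
  immune = "immune",
  caf = "caf",
  background = character(0)
)

# Linear-scale expression profile of one compartment at a given elevation.
.profile_linear <- function(blocks, profile, delta, baseline_log2) {
  base <- 2^baseline_log2
  elev <- blocks %in% .profile_elevates[[profile]]
  base * (1 + (2^delta - 1) * elev)
}

.tissue_bases <- c(primary_tumor = 0, cell_line = 1e6, pdx = 2e6, caf = 3e6,
                   normal_pancreas = 4e6, acc = 5e6, metastasis = 6e6,
                   normal_other = 7e6)

# Per-sample substream draws, always in the same order so streams are
# replayable independently of which draws a tissue type consumes.
.sample_draws <- function(config, tissue, index, n_genes) {
  set.seed(.substream_seed(config$seed, .tissue_bases[[tissue]] + index))
  u_subtype <- stats::runif(1)
  p_primary <- stats::rbeta(1, config$purity_alpha, config$purity_beta)
  p_acc <- stats::rbeta(1, config$acc_purity_alpha, config$acc_purity_beta)
  g <- stats::rgamma(3, shape = config$contamination_alpha)
  strength <- stats::rlnorm(1, meanlog = 0, sdlog = config$tumor_strength_sdlog)
  noise <- stats::rnorm(n_genes)
  list(subtype = if (u_subtype < config$subtype_fraction_basal) "basal"
                 else "classical",
       p_primary = p_primary, p_acc = p_acc,
       dirichlet = g / sum(g), strength = strength, noise = noise)
}

#' Generate a synthetic bulk-expression cohort with ground truth
#'
#' Each sample's linear-scale expression is a weighted sum of compartment
#' profiles: neoplastic weight `p` on the tumor profile of its subtype
#' (elevation scaled by the tumor's intrinsic strength) plus non-negative
#' contamination weights summing to `1 - p`, then observed as
#' `log2(x + 1) + N(0, noise_sd)`. Tissue rules: cell lines and PDXs are
#' (near-)pure tumor; CAF lines are pure fibroblast; normal pancreas is
#' acinar-dominated; acinar cell carcinomas are high-purity tumors whose
#' tumor profile is acinar-like; metastases carry non-pancreas background
#' contamination. Paired cell lines/metastases share their source primary's
#' subtype and strength through a `pair_id`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (log2-scale
#'   [expression_dataset()] with metadata), `truth` (a `synthetic_truth`
#'   object: per-sample purity, subtype, strength and compartment weights,
#'   per-gene block labels, config echo) and `gene_sets` (a
#'   [gene_set_collection()] of simulated signatures, including the
#'   deliberately mixed ADEX-like and immunogenic lists).
#' @export
generate_cohort <- function(config = simulation_config()) {
  .assert(inherits(config, "simulation_config"),
          "config must come from simulation_config()")
  blocks <- .gene_blocks(config)
  genes <- names(blocks)
  n_genes <- length(genes)
  base <- 2^config$baseline_log2

  n_cl_paired <- min(round(config$paired_fraction * config$n_cell_line),
                     config$n_primary)
  n_met_paired <- min(round(config$paired_fraction * config$n_metastasis),
                      config$n_primary - n_cl_paired)

  plan <- data.frame(
    tissue_type = rep(c("primary_tumor", "cell_line", "pdx", "caf",
                        "normal_pancreas", "acc", "metastasis",
                        "normal_other"),
                      times = c(config$n_primary, config$n_cell_line,
                                config$n_pdx, config$n_caf,
                                config$n_normal_pancreas, config$n_acc,
                                config$n_metastasis, config$n_normal_other)),
    stringsAsFactors = FALSE)
  plan$index <- unlist(lapply(table(factor(plan$tissue_type,
                                           levels = unique(plan$tissue_type))),
                              seq_len), use.names = FALSE)
  abbrev <- c(primary_tumor = "PT", cell_line = "CL", pdx = "PDX",
              caf = "CAF", normal_pancreas = "NP", acc = "ACC",
              metastasis = "MET", normal_other = "NO")
  plan$sample_id <- sprintf("%s_%03d", abbrev[plan$tissue_type], plan$index)
  n_samples <- nrow(plan)
  .assert(n_samples > 0, "all-zero cohort: no samples requested")

  values <- matrix(NA_real_, nrow = n_genes, ncol = n_samples,
                   dimnames = list(genes, plan$sample_id))
  truth <- data.frame(sample_id = plan$sample_id,
                      tissue_type = plan$tissue_type,
                      purity = NA_real_, subtype = NA_character_,
                      strength = NA_real_,
                      w_acinar = 0, w_immune = 0, w_caf = 0, w_background = 0,
                      pair_id = NA_character_, stringsAsFactors = FALSE)

  # Primaries first: derived samples inherit their subtype and strength.
  prim_subtype <- character(config$n_primary)
  prim_strength <- numeric(config$n_primary)

  lin_profile <- function(profile, delta_use) {
    .profile_linear(blocks, profile, delta_use, config$baseline_log2)
  }
  contam_profiles <- c("acinar", "immune", "caf")
  contam_linear <- vapply(contam_profiles, lin_profile,
                          numeric(n_genes), delta_use = config$delta)
  background_linear <- rep(base, n_genes)

  for (r in seq_len(n_samples)) {
    tt <- plan$tissue_type[r]
    i <- plan$index[r]
    dr <- .sample_draws(config, tt, i, n_genes)
    subtype <- dr$subtype
    strength <- dr$strength
    pair_id <- NA_character_

    if (tt == "primary_tumor") {
      prim_subtype[i] <- subtype
      prim_strength[i] <- strength
      p <- dr$p_primary
      w <- (1 - p) * dr$dirichlet
      lin <- p * lin_profile(paste0("tumor_", subtype),
                             config$delta * strength) +
        contam_linear %*% w
      if (i <= n_cl_paired) pair_id <- sprintf("pairCL_%03d", i)
      if (i > n_cl_paired && i <= n_cl_paired + n_met_paired)
        pair_id <- sprintf("pairMET_%03d", i - n_cl_paired)
      truth[r, c("w_acinar", "w_immune", "w_caf")] <- w
    } else if (tt == "cell_line") {
      if (i <= n_cl_paired) {
        subtype <- prim_subtype[i]
        strength <- prim_strength[i]
        pair_id <- sprintf("pairCL_%03d", i)
      }
      p <- 1
      lin <- lin_profile(paste0("tumor_", subtype), config$delta * strength)
    } else if (tt == "pdx") {
      p <- 1 - config$pdx_caf_weight
      lin <- p * lin_profile(paste0("tumor_", subtype),
                             config$delta * strength) +
        config$pdx_caf_weight * contam_linear[, "caf"]
      truth[r, "w_caf"] <- config$pdx_caf_weight
    } else if (tt == "caf") {
      p <- 0
      subtype <- NA_character_
      lin <- contam_linear[, "caf"]
      truth[r, "w_caf"] <- 1
    } else if (tt == "normal_pancreas") {
      p <- 0
      subtype <- NA_character_
      w <- config$normal_pancreas_weights
      lin <- contam_linear %*% w[contam_profiles]
      truth[r, c("w_acinar", "w_immune", "w_caf")] <- w[contam_profiles]
    } else if (tt == "acc") {
      # High-purity tumor whose neoplastic profile is acinar-like.
      p <- dr$p_acc
      w <- (1 - p) * dr$dirichlet
      lin <- p * lin_profile("acinar", config$delta * strength) +
        contam_linear %*% w
      subtype <- NA_character_
      truth[r, c("w_acinar", "w_immune", "w_caf")] <- w
    } else if (tt == "metastasis") {
      if (i <= n_met_paired) {
        subtype <- prim_subtype[n_cl_paired + i]
        strength <- prim_strength[n_cl_paired + i]
        pair_id <- sprintf("pairMET_%03d", i)
      }
      p <- dr$p_primary
      lin <- p * lin_profile(paste0("tumor_", subtype),
                             config$delta * strength) +
        (1 - p) * background_linear
      truth[r, "w_background"] <- 1 - p
    } else { # normal_other: non-pancreas normal tissue
      p <- 0
      subtype <- NA_character_
      lin <- 0.85 * background_linear +
        contam_linear %*% c(acinar = 0, immune = 0.10, caf = 0.05)
      truth[r, c("w_immune", "w_caf", "w_background")] <- c(0.10, 0.05, 0.85)
    }

    values[, r] <- log2(as.numeric(lin) + 1) + config$noise_sd * dr$noise
    truth$purity[r] <- p
    truth$subtype[r] <- subtype
    truth$strength[r] <- strength
    truth$pair_id[r] <- pair_id
  }

  metadata <- data.frame(
    sample_id = truth$sample_id,
    tissue_type = truth$tissue_type,
    histology_confirmed = ifelse(
      truth$tissue_type %in% c("primary_tumor", "metastasis", "cell_line",
                               "pdx"), TRUE,
      ifelse(truth$tissue_type == "acc", FALSE, NA)),
    purity = truth$purity,
    purity_source = "simulation_truth",
    pair_id = truth$pair_id,
    known_subtype = truth$subtype,
    stringsAsFactors = FALSE)

  dataset <- expression_dataset(values, scale = "log2", pseudocount = 1,
                                metadata = metadata)

  truth_obj <- structure(
    list(samples = truth, gene_blocks = blocks, config = config,
         seed = config$seed),
    class = "synthetic_truth")

  list(dataset = dataset,
       truth = truth_obj,
       gene_sets = .simulated_gene_sets(config, blocks))
}

.simulated_gene_sets <- function(config, blocks) {
  by_block <- split(names(blocks), blocks)
  bg <- by_block$background
  n_imm_extra <- round(config$immunogenic_classical_fraction /
                         (1 - config$immunogenic_classical_fraction) *
                         length(by_block$immune))
  hk_from <- config$adex_background_genes + 1
  gene_set_collection(list(
    gene_set("sim_basal", by_block$tumor_basal,
             source = "simulated tumor-basal block"),
    gene_set("sim_classical", by_block$tumor_classical,
             source = "simulated tumor-classical block"),
    gene_set("sim_tumor_shared", by_block$tumor_shared,
             source = "simulated tumor-shared block"),
    gene_set("sim_ADEX-like",
             c(by_block$acinar, bg[seq_len(config$adex_background_genes)]),
             source = "simulated acinar block plus nonspecific genes"),
    gene_set("sim_immunogenic",
             c(by_block$immune,
               by_block$tumor_classical[seq_len(n_imm_extra)]),
             source = "simulated immune block plus tumor-classical overlap"),
    gene_set("sim_CAF", by_block$caf, source = "simulated fibroblast block"),
    gene_set("sim_housekeeping",
             bg[seq(hk_from, hk_from + config$housekeeping_set_size - 1)],
             source = "simulated housekeeping background")
  ))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d samples, %d genes, seed %s\n",
              nrow(x$samples), length(x$gene_blocks), format(x$seed)))
  print(table(x$samples$tissue_type))
  invisible(x)
}

#' Analytic expectation of the score-on-purity regression slope
#'
#' For a compartment gene block, returns the expected least-squares slope of
#' the block's gene-set score (mean log2 expression) on neoplastic purity
#' across primary tumors under the mixture model, evaluated by deterministic
#' high-resolution numerical integration over the purity, contamination-split,
#' subtype and strength distributions (the additive log2-scale noise has mean
#' zero and does not enter the slope). Contamination blocks yield negative
#' slopes, the tumor-shared block a positive slope, and subtype-private tumor
#' blocks a subtype-mix-dependent slope.
#'
#' @param config A [simulation_config()].
#' @param block One of `"tumor_shared"`, `"tumor_basal"`,
#'   `"tumor_classical"`, `"acinar"`, `"immune"`, `"caf"`, `"background"`.
#' @param n_draws Number of integration draws.
#' @return Expected slope (log2 units per unit purity).
#' @export
expected_score_slope <- function(config, block, n_draws = 2e5) {
  .assert(inherits(config, "simulation_config"),
          "config must come from simulation_config()")
  allowed <- names(.block_prefix)
  .assert(length(block) == 1 && block %in% allowed,
          "unknown block '", block, "'; expected one of: ",
          paste(allowed, collapse = ", "))
  base <- 2^config$baseline_log2
  up <- 2^config$delta - 1
  set.seed(.substream_seed(config$seed, 999983))
  p <- stats::rbeta(n_draws, config$purity_alpha, config$purity_beta)
  g <- matrix(stats::rgamma(3L * n_draws,
                            shape = rep(config$contamination_alpha,
                                        each = n_draws)),
              ncol = 3)
  d <- g / rowSums(g)
  basal <- stats::runif(n_draws) < config$subtype_fraction_basal
  st <- stats::rlnorm(n_draws, 0, config$tumor_strength_sdlog)
  up_i <- 2^(config$delta * st) - 1

  lin <- switch(block,
    tumor_shared = base * (1 + p * up_i),
    tumor_basal = base * (1 + p * up_i * basal),
    tumor_classical = base * (1 + p * up_i * !basal),
    acinar = base * (1 + (1 - p) * d[, 1] * up),
    immune = base * (1 + (1 - p) * d[, 2] * up),
    caf = base * (1 + (1 - p) * d[, 3] * up),
    background = rep(base, n_draws))
  score <- log2(lin + 1)
  stats::cov(score, p) / stats::var(p)
}

#' Write a synthetic cohort to disk
#'
#' Writes the standard trio (expression TSV, metadata TSV, gene sets GMT)
#' plus a ground-truth JSON, consumable unchanged by the downstream modules.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$dataset, paths[["expression"]])
  write_metadata(cohort$dataset$metadata, paths[["metadata"]])
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(samples = truth$samples,
         gene_blocks = as.list(truth$gene_blocks),
         config = unclass(truth$config),
         note = paste("synthetic ground truth; compartment weights are",
                      "plausibility choices, not estimates from real tumors")),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
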