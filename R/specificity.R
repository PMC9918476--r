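# Specificity statistics: purity correlation, compartment contrasts, paired
# retention, overlap/concordance, and the tumor-intrinsic verdict.

#' Correlation of a gene-set score with tumor purity
#'
#' Spearman correlation of the score against the metadata `purity` column,
#' restricted to samples with purity present (missing purity drops the
#' sample pairwise, never imputed).
#'
#' @param score A `score_vector` (named by sample id).
#' @param metadata Data.frame with `sample_id` and `purity` columns.
#' @return List with `rho`, `p`, `n_used`.
#' @export
purity_correlation <- function(score, metadata) {
  .assert("purity" %in% names(metadata), "metadata lacks a 'purity' column")
  idx <- match(names(score), metadata$sample_id)
  .assert(!anyNA(idx), "score samples missing from metadata")
  purity <- metadata$purity[idx]
  usable <- sum(is.finite(purity) & is.finite(as.numeric(score)))
  .assert(usable >= 3, "need >= 3 samples with purity (have ", usable, ")")
  res <- spearman_rho(as.numeric(score), purity)
  list(rho = res$rho, p = res$p, n_used = res$n_used)
}

#' Compartment contrast panel
#'
#' For each gene set and each requested tissue-type contrast, compares
#' mean standardized scores between the two groups with the Wilcoxon
#' rank-sum test. Scores are standardized per set over **all** samples in
#' `score_table` (the standardization cohort is recorded on the result).
#'
#' @param score_table Long-format table from [score_panel()]
#'   (unstandardized scores are standardized here; already-standardized
#'   tables are used as-is).
#' @param metadata Data.frame with `sample_id` and `tissue_type`.
#' @param contrasts List of 2-element character vectors
#'   `c(group_a, group_b)` of tissue-type levels.
#' @param adjust Apply Benjamini-Hochberg adjustment across the table
#'   (column `p_adj`); the default reports raw two-sided p-values.
#' @return Data.frame with one row per (gene set, contrast): group ns,
#'   group means, rank-sum statistic, two-sided `p` (and `p_adj` when
#'   requested). The standardization cohort is in
#'   `attr(, "standardization_cohort")`.
#' @export
compartment_panel <- function(score_table, metadata, contrasts,
                              adjust = FALSE) {
  .assert(all(c("sample_id", "gene_set", "score") %in% names(score_table)),
          "score_table must come from score_panel()")
  .assert("tissue_type" %in% names(metadata),
          "metadata lacks a 'tissue_type' column")
  .assert(is.list(contrasts) && length(contrasts) >= 1 &&
            all(lengths(contrasts) == 2),
          "contrasts must be a list of c(group_a, group_b) pairs")
  levels_present <- unique(metadata$tissue_type)
  for (ct in contrasts) {
    missing <- setdiff(ct, levels_present)
    .assert(length(missing) == 0,
            "contrast references unknown tissue_type(s): ",
            paste(missing, collapse = ", "))
  }
  tissue <- metadata$tissue_type[match(score_table$sample_id,
                                       metadata$sample_id)]
  cohort <- sprintf("all_scored_samples(n=%d)",
                    length(unique(score_table$sample_id)))
  rows <- list()
  for (set_name in unique(score_table$gene_set)) {
    sel <- score_table$gene_set == set_name
    z <- score_table$score[sel]
    if (!all(score_table$standardized[sel])) {
      z <- as.numeric(standardize_scores(z))
    }
    tt <- tissue[sel]
    for (ct in contrasts) {
      ga <- z[tt %in% ct[1]]
      gb <- z[tt %in% ct[2]]
      .assert(length(ga) >= 1 && length(gb) >= 1,
              "empty contrast group for set '", set_name, "': ",
              ct[1], " vs ", ct[2])
      ts <- rank_sum_test(ga, gb)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_set = set_name, group_a = ct[1], group_b = ct[2],
        n_a = length(ga), n_b = length(gb),
        mean_a = mean(ga), mean_b = mean(gb),
        statistic = ts$statistic, p = ts$p, method = ts$method,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "standardization_cohort") <- cohort
  out
}

#' Paired retention of a signature from primaries to derived samples
#'
#' For pairs (via `pair_id`) with one sample of the source tissue type and
#' one of the derived type, reports the Spearman correlation of derived
#' scores on source scores across pairs, plus a loss summary
#' `mean(derived) - mean(source)` in standardized units. Scores are
#' standardized over all samples in the score vector (the full scored
#' cohort) unless already standardized.
#'
#' @param score A `score_vector` named by sample id.
#' @param metadata Data.frame with `sample_id`, `tissue_type`, `pair_id`.
#' @param source_type,derived_type Tissue types of the pair members.
#' @return List with `rho`, `p`, `n_pairs`, `loss`, `pairs` (per-pair
#'   table), `n_skipped` (pair ids lacking one of the two roles).
#' @export
paired_retention <- function(score, metadata,
                             source_type = "primary_tumor",
                             derived_type = "cell_line") {
  .assert(all(c("pair_id", "tissue_type") %in% names(metadata)),
          "metadata needs 'pair_id' and 'tissue_type'")
  if (!isTRUE(attr(score, "standardized"))) {
    score <- standardize_scores(score)
  }
  md <- metadata[!is.na(metadata$pair_id), , drop = FALSE]
  md <- md[md$tissue_type %in% c(source_type, derived_type), , drop = FALSE]
  pairs <- list()
  n_skipped <- 0L
  for (pid in unique(md$pair_id)) {
    grp <- md[md$pair_id == pid, , drop = FALSE]
    src <- grp$sample_id[grp$tissue_type == source_type]
    der <- grp$sample_id[grp$tissue_type == derived_type]
    if (length(src) > 1 || length(der) > 1) {
      stop("pair '", pid, "' has duplicated roles", call. = FALSE)
    }
    if (length(src) != 1 || length(der) != 1 ||
        !(src %in% names(score)) || !(der %in% names(score))) {
      n_skipped <- n_skipped + 1L
      next
    }
    pairs[[pid]] <- data.frame(pair_id = pid, source_id = src,
                               derived_id = der,
                               source_score = as.numeric(score[src]),
                               derived_score = as.numeric(score[der]),
                               stringsAsFactors = FALSE)
  }
  .assert(length(pairs) >= 3,
          "need >= 3 usable ", source_type, "/", derived_type,
          " pairs (have ", length(pairs), ")")
  tab <- do.call(rbind, c(pairs, make.row.names = FALSE))
  res <- spearman_rho(tab$source_score, tab$derived_score)
  list(rho = res$rho, p = res$p, n_pairs = nrow(tab),
       loss = mean(tab$derived_score) - mean(tab$source_score),
       pairs = tab, n_skipped = n_skipped)
}

#' Overlap between two gene lists
#'
#' Asymmetric: the fraction is relative to the first list
#' (`|A intersect B| / |A|`).
#'
#' @param set_a,set_b [gene_set()] objects or character vectors.
#' @return List with `count` and `fraction_of_a`.
#' @export
gene_list_overlap <- function(set_a, set_b) {
  a <- if (inherits(set_a, "gene_set")) set_a$genes else unique(as.character(set_a))
  b <- if (inherits(set_b, "gene_set")) set_b$genes else unique(as.character(set_b))
  .assert(length(a) >= 1 && length(b) >= 1, "both gene lists must be non-empty")
  count <- length(intersect(a, b))
  list(count = count, fraction_of_a = count / length(a))
}

#' Concordance between two sample labelings
#'
#' Fraction of samples whose labels agree after mapping `labels_b`'s
#' vocabulary onto `labels_a`'s. When no mapping is supplied it is inferred
#' by maximal-agreement matching (greedy on the contingency table).
#'
#' @param labels_a,labels_b Named character vectors over the same sample ids.
#' @param mapping Optional named character vector mapping levels of
#'   `labels_b` to levels of `labels_a`.
#' @return List with `concordance` and the `mapping` used.
#' @export
label_concordance <- function(labels_a, labels_b, mapping = NULL) {
  .assert(!is.null(names(labels_a)) && !is.null(names(labels_b)),
          "label vectors must be named by sample id")
  .assert(setequal(names(labels_a), names(labels_b)),
          "label vectors cover different sample ids")
  labels_b <- labels_b[names(labels_a)]
  if (is.null(mapping)) {
    tab <- table(b = labels_b, a = labels_a)
    mapping <- character(0)
    while (nrow(tab) > 0 && ncol(tab) > 0) {
      ij <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
      mapping[rownames(tab)[ij[1L]]] <- colnames(tab)[ij[2L]]
      tab <- tab[-ij[1L], -ij[2L], drop = FALSE]
    }
  }
  mapped <- unname(mapping[as.character(labels_b)])
  agree <- mapped == as.character(labels_a)
  agree[is.na(agree)] <- FALSE # labels with no mapped counterpart disagree
  list(concordance = mean(agree), mapping = mapping)
}

#' Default verdict rules
#'
#' Thresholds are artifact configuration (echoed in every report), not
#' field-established constants: the underlying findings are directional.
#'
#' @param rho_threshold Purity-correlation threshold below which a
#'   significant negative correlation flags contamination.
#' @param p_threshold Significance level for the purity correlation and the
#'   primary-vs-derived contrast.
#' @return A named list of class `verdict_rules`.
#' @export
verdict_rules <- function(rho_threshold = -0.1, p_threshold = 0.05) {
  structure(list(rho_threshold = rho_threshold, p_threshold = p_threshold),
            class = "verdict_rules")
}

#' Tumor-intrinsic verdict for one signature
#'
#' Operationalizes the specificity evidence into a categorical call:
#' * `non_tumor` if the score is significantly negatively correlated with
#'   purity (`rho <= rho_threshold` and `p < p_threshold`), or the derived
#'   (cell-line) mean is significantly below the primary mean **and** the
#'   paired loss is negative;
#' * `tumor_intrinsic` if cell-line retention holds (no significant loss)
#'   and the purity correlation is above `rho_threshold`;
#' * `ambiguous` otherwise, or when required evidence is missing.
#'
#' @param fragment List with any of: `purity_rho`, `purity_p`, `contrast`
#'   (list with `mean_primary`, `mean_derived`, `p`), `paired_loss`.
#' @param rules A [verdict_rules()] object.
#' @return List with `verdict`, `rules_fired` (machine-readable rule ids)
#'   and `rules` (the thresholds used, echoed).
#' @export
signature_verdict <- function(fragment, rules = verdict_rules()) {
  .assert(inherits(rules, "verdict_rules"), "rules must come from verdict_rules()")
  has_purity <- !is.null(fragment$purity_rho) && !is.null(fragment$purity_p) &&
    is.finite(fragment$purity_rho) && is.finite(fragment$purity_p)
  ctr <- fragment$contrast
  has_contrast <- !is.null(ctr) && is.finite(ctr$mean_primary %||% NA) &&
    is.finite(ctr$mean_derived %||% NA) && is.finite(ctr$p %||% NA)
  has_loss <- !is.null(fragment$paired_loss) && is.finite(fragment$paired_loss)

  fired <- character(0)
  if (!has_purity && !has_contrast) {
    return(list(verdict = "ambiguous", rules_fired = "insufficient_evidence",
                rules = rules))
  }
  purity_confounded <- has_purity &&
    fragment$purity_rho <= rules$rho_threshold &&
    fragment$purity_p < rules$p_threshold
  significant_loss <- has_contrast &&
    ctr$mean_derived < ctr$mean_primary && ctr$p < rules$p_threshold
  paired_loss_negative <- has_loss && fragment$paired_loss < 0

  if (purity_confounded) fired <- c(fired, "purity_confounded")
  if (significant_loss && paired_loss_negative)
    fired <- c(fired, "derived_model_loss")

  verdict <- if (purity_confounded ||
                 (significant_loss && paired_loss_negative)) {
    "non_tumor"
  } else if (has_contrast && !significant_loss && has_purity &&
             fragment$purity_rho > rules$rho_threshold) {
    fired <- c(fired, "retention_holds", "no_purity_confounding")
    "tumor_intrinsic"
  } else {
    fired <- c(fired, "inconclusive_evidence")
    "ambiguous"
  }
  list(verdict = verdict, rules_fired = fired, rules = rules)
}

#' Signature robustness panel
#'
#' For each gene set: size, dataset coverage, per-tissue-type mean
#' standardized score, and the spread (max - min) of those tissue means. A
#' large spread across non-tumor tissues flags non-specificity; long lists
#' accumulate off-target compartment signal.
#'
#' @param collection A [gene_set_collection()].
#' @param dataset A log2-scale [expression_dataset()] with `tissue_type`
#'   metadata.
#' @return Data.frame with columns `gene_set`, `size`, `coverage`, one
#'   `mean.<tissue_type>` column per tissue level, and `spread`. Failing
#'   sets are recorded in `attr(, "failures")`.
#' @export
signature_robustness_panel <- function(collection, dataset) {
  .assert("tissue_type" %in% names(dataset$metadata),
          "dataset metadata lacks 'tissue_type'")
  tissue <- dataset$metadata$tissue_type
  levels_t <- unique(tissue[!is.na(tissue)])
  rows <- list()
  failures <- data.frame(gene_set = character(0), error = character(0),
                         stringsAsFactors = FALSE)
  for (set in collection) {
    sv <- tryCatch(standardize_scores(gene_set_score(dataset, set,
                                                     verbose = FALSE)),
                   error = function(e) e)
    if (inherits(sv, "error")) {
      failures <- rbind(failures,
                        data.frame(gene_set = set$name,
                                   error = conditionMessage(sv),
                                   stringsAsFactors = FALSE))
      next
    }
    means <- vapply(levels_t, function(tt) {
      mean(sv[which(tissue == tt)])
    }, numeric(1))
    row <- data.frame(gene_set = set$name, size = length(set$genes),
                      coverage = attr(sv, "coverage"),
                      stringsAsFactors = FALSE)
    for (tt in levels_t) row[[paste0("mean.", tt)]] <- means[[tt]]
    row$spread <- max(means) - min(means)
    rows[[set$name]] <- row
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "failures") <- failures
  out
}
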