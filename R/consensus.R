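# Resampled k-means consensus clustering, implemented from scratch.
#
# For each resample a subsample of items is drawn without replacement, a
# restarted k-means (k-means++ seeding, best inertia kept) partitions it, and
# co-cluster / co-sampling tallies are accumulated. The consensus matrix is
# the elementwise tally ratio; the final partition cuts an average-linkage
# dendrogram of (1 - consensus) into k groups.

# k-means++ style seeding: first center uniform, later centers with
# probability proportional to squared distance to the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      idx <- if (sum(d2) <= 0) {
        sample.int(n, 1L)
      } else {
        sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2_new <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, d2_new)
    }
  }
  centers
}

# Restarted Lloyd k-means on Euclidean distance; returns the labelling with
# the lowest total within-cluster sum of squares. An empty-cluster failure is
# re-seeded once before erroring.
.kmeans_best <- function(x, k, restarts = 10, iter_max = 300) {
  if (k == 1L) return(rep(1L, nrow(x)))
  best <- NULL
  best_wss <- Inf
  for (r in seq_len(restarts)) {
    centers <- .kmeanspp_centers(x, k)
    if (anyDuplicated(centers)) {
      # duplicated item rows can collapse centers; fall back to distinct rows
      ux <- unique(x)
      if (nrow(ux) >= k) centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    }
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) e)
    if (inherits(km, "error")) {
      centers <- .kmeanspp_centers(x, k)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) stop("k-means failed after re-seeding: ",
                                 conditionMessage(e), call. = FALSE))
    }
    if (km$tot.withinss < best_wss) {
      best_wss <- km$tot.withinss
      best <- km$cluster
    }
  }
  best
}

#' Resampled k-means consensus clustering
#'
#' @param x Numeric matrix, rows = items to cluster, columns = features
#'   (Euclidean distance).
#' @param k Number of clusters (`1 <= k <=` number of items).
#' @param resamples Number of subsampling rounds.
#' @param subsample_fraction Fraction of items drawn (without replacement)
#'   per round.
#' @param seed Master seed; each resample runs on a deterministic substream
#'   so results are reproducible and rounds are independent of each other.
#' @param restarts k-means restarts per round (k-means++ seeding, best
#'   inertia kept).
#' @param iter_max Lloyd iteration cap per k-means run.
#'
#' @return A `consensus_result` with elements `items`, `k`, `M` (consensus
#'   matrix: co-cluster count / co-sampling count, diagonal 1), `N`
#'   (co-sampling counts), `assignments` (average-linkage cut of `1 - M`
#'   into k groups), `resamples`, `subsample_fraction`, `seed`, `hclust`.
#'   Item pairs never co-sampled (impossible at default settings) get
#'   consensus 0 with a warning.
#' @export
consensus_cluster <- function(x, k, resamples = 1000,
                              subsample_fraction = 0.8, seed = 1,
                              restarts = 10, iter_max = 300) {
  .assert(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  n <- nrow(x)
  items <- rownames(x) %||% as.character(seq_len(n))
  .assert(k >= 1 && k <= n, "need items >= k >= 1 (n = ", n, ", k = ", k, ")")
  .assert(subsample_fraction > 0 && subsample_fraction <= 1,
          "subsample_fraction must be in (0, 1]")
  .assert(resamples >= 1, "resamples must be >= 1")
  m <- ceiling(subsample_fraction * n)
  .assert(m >= k, "subsample size ", m, " is smaller than k = ", k)

  C <- matrix(0, n, n)
  N <- matrix(0, n, n)
  for (b in seq_len(resamples)) {
    set.seed(.substream_seed(seed, b))
    idx <- sample.int(n, m)
    labels <- .kmeans_best(x[idx, , drop = FALSE], k,
                           restarts = restarts, iter_max = iter_max)
    same <- outer(labels, labels, "==")
    C[idx, idx] <- C[idx, idx] + same
    N[idx, idx] <- N[idx, idx] + 1
  }
  M <- matrix(0, n, n)
  sampled <- N > 0
  M[sampled] <- C[sampled] / N[sampled]
  if (any(N[upper.tri(N)] == 0)) {
    warning("some item pairs were never co-sampled; their consensus is 0 ",
            "(increase resamples or subsample_fraction)", call. = FALSE)
  }
  diag(M) <- 1
  dimnames(M) <- dimnames(N) <- list(items, items)

  hc <- NULL
  assignments <- if (n == 1L) {
    stats::setNames(1L, items)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
    stats::setNames(stats::cutree(hc, k = k), items)
  }
  structure(
    list(items = items, k = k, M = M, N = N, assignments = assignments,
         resamples = resamples, subsample_fraction = subsample_fraction,
         seed = seed,
         hclust = hc),
    class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d items, k = %d, %d resamples (f = %.2f, seed %s)\n",
              length(x$items), x$k, x$resamples, x$subsample_fraction,
              format(x$seed)))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Write a consensus result to disk
#'
#' Consensus matrix and assignments as TSV, parameters as a JSON sidecar.
#'
#' @param result A `consensus_result`.
#' @param prefix Path prefix; writes `<prefix>_consensus.tsv`,
#'   `<prefix>_assignments.tsv`, `<prefix>_params.json`.
#' @return Named vector of paths, invisibly.
#' @export
write_consensus <- function(result, prefix) {
  paths <- c(consensus = paste0(prefix, "_consensus.tsv"),
             assignments = paste0(prefix, "_assignments.tsv"),
             params = paste0(prefix, "_params.json"))
  m <- result$M
  con <- file(paths[["consensus"]], open = "wb")
  writeLines(c(paste(c("item", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i) {
                 paste(c(rownames(m)[i], .format_full(m[i, ])), collapse = "\t")
               }, character(1))), con, sep = "\n", useBytes = TRUE)
  close(con)
  con <- file(paths[["assignments"]], open = "wb")
  writeLines(c("item\tcluster",
               paste(result$items, result$assignments, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  close(con)
  jsonlite::write_json(
    list(k = result$k, resamples = result$resamples,
         subsample_fraction = result$subsample_fraction, seed = result$seed),
    paths[["params"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Center and scale matrix rows; constant rows become all-zero rather than NaN.
.scale_rows <- function(v) {
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  (v - mu) / sd
}

#' Consensus subtype assignment of samples
#'
#' Restricts the dataset to the union of the collection's genes, clusters the
#' samples by resampled k-means consensus with `k = ` number of gene sets
#' (each gene row centered/scaled across samples first, so no single
#' high-magnitude gene dominates the Euclidean distance), then names each
#' cluster after a gene set: clusters take the set with the highest mean
#' standardized score among their members, resolved one-to-one greedily in
#' decreasing order of each cluster's score margin (best minus second-best),
#' with ties broken by collection order.
#'
#' @param dataset A log2-scale [expression_dataset()].
#' @param collection A non-empty [gene_set_collection()].
#' @param resamples,subsample_fraction,seed,restarts Passed to
#'   [consensus_cluster()].
#' @param scale_genes Center/scale gene rows before clustering.
#' @return A `subtype_assignment`: list with `labels` (named by sample),
#'   `mapping` (cluster -> gene set), `score_means` (cluster x set matrix of
#'   mean standardized scores) and `consensus` (the `consensus_result`).
#' @export
assign_subtypes <- function(dataset, collection, resamples = 250,
                            subsample_fraction = 0.8, seed = 1,
                            restarts = 10, scale_genes = TRUE) {
  .assert(inherits(collection, "gene_set_collection") && length(collection) >= 1,
          "collection must be a non-empty gene_set_collection")
  .assert(dataset$scale == "log2", "dataset must be log2-scaled")
  genes <- intersect(unique(unlist(lapply(collection, `[[`, "genes"))),
                     rownames(dataset$values))
  .assert(length(genes) >= 1, "no collection genes present in the dataset")
  k <- length(collection)
  .assert(ncol(dataset$values) >= k,
          "fewer samples than gene sets (k = ", k, ")")
  v <- dataset$values[genes, , drop = FALSE]
  if (scale_genes) v <- .scale_rows(v)
  cc <- consensus_cluster(t(v), k = k, resamples = resamples,
                          subsample_fraction = subsample_fraction,
                          seed = seed, restarts = restarts)

  score_means <- matrix(NA_real_, nrow = k, ncol = length(collection),
                        dimnames = list(paste0("cluster", seq_len(k)),
                                        names(collection)))
  for (set in collection) {
    sv <- standardize_scores(gene_set_score(dataset, set, verbose = FALSE))
    for (cl in seq_len(k)) {
      score_means[cl, set$name] <- mean(sv[cc$assignments == cl])
    }
  }

  # Greedy one-to-one cluster -> set mapping on sorted score margins.
  margin <- apply(score_means, 1L, function(row) {
    if (length(row) == 1L) return(Inf)
    s <- sort(row, decreasing = TRUE)
    s[1L] - s[2L]
  })
  mapping <- character(k)
  available <- names(collection)
  for (cl in order(-margin, seq_len(k))) {
    row <- score_means[cl, available, drop = TRUE]
    # which.max takes the first maximum: ties resolve by collection order
    pick <- available[which.max(row)]
    mapping[cl] <- pick
    available <- setdiff(available, pick)
  }
  labels <- stats::setNames(mapping[cc$assignments], cc$items)
  structure(list(labels = labels, mapping = mapping,
                 score_means = score_means, consensus = cc),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("subtype_assignment:\n")
  print(table(x$labels))
  invisible(x)
}

#' Gene-based consensus decomposition of a signature
#'
#' Clusters the genes of one signature (items = genes, features = samples,
#' gene rows centered/scaled) by resampled k-means consensus, and summarizes
#' each gene cluster's mean log2 expression per tissue type so callers can
#' label clusters (e.g. "ACC-specific", "nonspecific").
#'
#' @param dataset A log2-scale [expression_dataset()] whose metadata carries
#'   `tissue_type`.
#' @param set A [gene_set()] with at least `k` genes present in the dataset.
#' @param k Number of gene clusters.
#' @param resamples,subsample_fraction,seed,restarts Passed to
#'   [consensus_cluster()].
#' @param scale_genes Center/scale gene rows before clustering.
#' @return A `signature_decomposition`: list with `clusters` (named gene ->
#'   cluster), `tissue_profile` (cluster x tissue-type matrix of mean
#'   unscaled log2 expression) and `consensus`.
#' @export
decompose_signature <- function(dataset, set, k, resamples = 250,
                                subsample_fraction = 0.8, seed = 1,
                                restarts = 10, scale_genes = TRUE) {
  .assert(inherits(set, "gene_set"), "'set' must be a gene_set")
  genes <- intersect(set$genes, rownames(dataset$values))
  .assert(length(genes) >= k,
          "gene set '", set$name, "' has ", length(genes),
          " genes in the dataset; need >= k = ", k)
  raw <- dataset$values[genes, , drop = FALSE]
  v <- if (scale_genes) .scale_rows(raw) else raw
  cc <- consensus_cluster(v, k = k, resamples = resamples,
                          subsample_fraction = subsample_fraction,
                          seed = seed, restarts = restarts)
  tissue <- dataset$metadata$tissue_type
  profile <- NULL
  if (!is.null(tissue)) {
    levels_t <- unique(tissue[!is.na(tissue)])
    profile <- matrix(NA_real_, nrow = k, ncol = length(levels_t),
                      dimnames = list(paste0("cluster", seq_len(k)), levels_t))
    for (cl in seq_len(k)) {
      sub <- raw[cc$assignments == cl, , drop = FALSE]
      for (tt in levels_t) {
        profile[cl, tt] <- mean(sub[, which(tissue == tt), drop = FALSE])
      }
    }
  }
  structure(list(clusters = cc$assignments, tissue_profile = profile,
                 consensus = cc),
            class = "signature_decomposition")
}

#' @export
print.signature_decomposition <- function(x, ...) {
  cat("signature_decomposition:\n")
  print(table(cluster = x$clusters))
  if (!is.null(x$tissue_profile)) {
    cat("mean log2 expression by tissue type:\n")
    print(round(x$tissue_profile, 2))
  }
  invisible(x)
}
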