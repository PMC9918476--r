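# Generic top-scoring-pairs (TSP) classifier: within-sample rank comparisons
# of gene pairs, hence single-sample and cohort-free by construction.

#' Train a top-scoring-pairs classifier
#'
#' Every ordered gene pair (a, b) is scored by
#' `|P(expr_a > expr_b | class1) - P(expr_a > expr_b | class2)|` on the
#' training cohort. The top `n_pairs` pairs are selected greedily in
#' decreasing score order (ties broken by lexicographic gene ids), with each
#' gene used at most once; each pair is oriented so that
#' `expr(g_up) > expr(g_down)` votes for the first class.
#'
#' @param dataset A log2-scale [expression_dataset()].
#' @param labels Two-class labels: a vector in column order or named by
#'   sample id; each class needs >= 5 samples. The first level (factor
#'   order, else sorted order) becomes class 1.
#' @param n_pairs Number of pairs to select (default 8: small fixed panels
#'   are the point of TSP classifiers).
#' @param genes Optional subset of genes to consider (defaults to all rows;
#'   pair search is O(genes^2 x samples)).
#' @return A `tsp_model`: list with `pairs` (data.frame `g_up`, `g_down`,
#'   `margin`), `classes` (class 1 first), `threshold` (vote fraction above
#'   which class 1 is called) and `provenance`.
#' @export
train_tsp <- function(dataset, labels, n_pairs = 8, genes = NULL) {
  .assert(inherits(dataset, "expression_dataset"), "not an expression_dataset")
  .assert(dataset$scale == "log2", "dataset must be log2-scaled")
  ids <- colnames(dataset$values)
  if (!is.null(names(labels))) {
    .assert(setequal(names(labels), ids), "label names must match sample ids")
    labels <- labels[ids]
  } else {
    .assert(length(labels) == length(ids),
            "labels must cover every sample")
  }
  classes <- if (is.factor(labels)) levels(droplevels(labels))
             else sort(unique(as.character(labels)))
  .assert(length(classes) == 2, "exactly two classes required")
  labels <- as.character(labels)
  .assert(all(table(labels) >= 5), "each class needs >= 5 training samples")

  v <- dataset$values
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(v))
    .assert(length(genes) >= 2, "fewer than 2 candidate genes present")
    v <- v[genes, , drop = FALSE]
  }
  g <- rownames(v)
  G <- length(g)

  # P(expr_a > expr_b | class): accumulate pairwise comparison frequencies.
  pgt <- function(cols) {
    acc <- matrix(0, G, G)
    for (j in cols) acc <- acc + (outer(v[, j], v[, j], ">") * 1)
    acc / length(cols)
  }
  p1 <- pgt(which(labels == classes[1]))
  p2 <- pgt(which(labels == classes[2]))
  margin <- abs(p1 - p2)
  diag(margin) <- -Inf

  ut <- which(upper.tri(margin), arr.ind = TRUE)
  # unordered pairs suffice: margin(a,b) counts a>b, margin(b,a) counts b>a;
  # keep the stronger direction of each pair as its candidate score
  cand <- data.frame(i = ut[, 1], j = ut[, 2],
                     m = pmax(margin[ut], margin[cbind(ut[, 2], ut[, 1])]))
  ord <- order(-cand$m, g[cand$i], g[cand$j])
  cand <- cand[ord, , drop = FALSE]

  used <- character(0)
  sel <- list()
  for (r in seq_len(nrow(cand))) {
    if (length(sel) == n_pairs) break
    a <- g[cand$i[r]]; b <- g[cand$j[r]]
    if (a %in% used || b %in% used) next
    # pick the better-scoring direction for this unordered pair
    if (margin[b, a] > margin[a, b]) { tmp <- a; a <- b; b <- tmp }
    # orient votes toward class 1
    if (p1[a, b] >= p2[a, b]) {
      pair <- c(a, b)
    } else {
      pair <- c(b, a)
    }
    sel[[length(sel) + 1L]] <- data.frame(g_up = pair[1], g_down = pair[2],
                                          margin = cand$m[r],
                                          stringsAsFactors = FALSE)
    used <- c(used, a, b)
  }
  .assert(length(sel) == n_pairs,
          "only ", length(sel), " admissible pairs found; requested ", n_pairs)
  structure(
    list(pairs = do.call(rbind, c(sel, make.row.names = FALSE)),
         classes = classes, threshold = 0.5,
         provenance = list(n_samples = length(labels),
                           class_counts = as.list(table(labels)),
                           n_candidate_genes = G)),
    class = "tsp_model")
}

#' @export
print.tsp_model <- function(x, ...) {
  cat(sprintf("tsp_model: %d pairs, classes %s (vote threshold %.2f)\n",
              nrow(x$pairs), paste(x$classes, collapse = " vs "), x$threshold))
  print(x$pairs)
  invisible(x)
}

#' Predict subtypes with a TSP model
#'
#' Each sample is classified entirely from within-sample comparisons: the
#' vote fraction is the fraction of pairs with `expr(g_up) > expr(g_down)`
#' (exact within-pair ties count 0.5), and class 1 is called when the vote
#' fraction exceeds the threshold (a vote fraction exactly at the threshold
#' calls class 2). Predictions are therefore invariant under any strictly
#' increasing transform of a sample's expression vector and identical
#' whether a sample is predicted alone or inside a batch.
#'
#' @param object A `tsp_model`.
#' @param newdata A named numeric vector (single sample), a genes x samples
#'   matrix, or an [expression_dataset()]. All model genes must be present;
#'   missing genes are an error, never imputed.
#' @param ... Unused.
#' @return Data.frame with `sample_id`, `label`, `vote_fraction`.
#' @export
predict.tsp_model <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "expression_dataset")) {
    newdata$values
  } else if (is.matrix(newdata)) {
    newdata
  } else {
    .assert(is.numeric(newdata) && !is.null(names(newdata)),
            "single-sample input must be a named numeric vector")
    matrix(newdata, ncol = 1, dimnames = list(names(newdata), "sample1"))
  }
  need <- unique(c(object$pairs$g_up, object$pairs$g_down))
  missing <- setdiff(need, rownames(v))
  .assert(length(missing) == 0,
          "model gene(s) missing from input: ", paste(missing, collapse = ", "))
  up <- v[object$pairs$g_up, , drop = FALSE]
  down <- v[object$pairs$g_down, , drop = FALSE]
  votes <- (up > down) + 0.5 * (up == down)
  frac <- colMeans(votes)
  data.frame(sample_id = colnames(v) %||% as.character(seq_along(frac)),
             label = ifelse(frac > object$threshold,
                            object$classes[1], object$classes[2]),
             vote_fraction = unname(frac),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize / restore a TSP model as JSON
#' @param model A `tsp_model`.
#' @param path Output path.
#' @return `path` invisibly (`write_tsp_model`) or a `tsp_model`
#'   (`read_tsp_model`).
#' @export
write_tsp_model <- function(model, path) {
  jsonlite::write_json(
    list(pairs = model$pairs, classes = model$classes,
         threshold = model$threshold, provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tsp_model
#' @export
read_tsp_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pairs = as.data.frame(raw$pairs),
                 classes = raw$classes, threshold = raw$threshold,
                 provenance = raw$provenance),
            class = "tsp_model")
}
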