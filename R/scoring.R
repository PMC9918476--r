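#' Gene-set score: mean log2 expression of a signature's genes
#'
#' The score of a sample is the arithmetic mean of the log2 expression of the
#' set's genes present in the dataset. Missing genes are reported through the
#' coverage attribute and a log line, never imputed.
#'
#' @param dataset A log2-scale [expression_dataset()].
#' @param set A [gene_set()].
#' @param verbose Log missing genes to stderr.
#' @return A `score_vector`: named numeric vector (one score per sample) with
#'   attributes `gene_set`, `matched_genes`, `coverage`, `standardized`
#'   (FALSE) and `cohort` (NULL until standardized).
#' @export
gene_set_score <- function(dataset, set, verbose = TRUE) {
  .assert(inherits(dataset, "expression_dataset"), "not an expression_dataset")
  .assert(inherits(set, "gene_set"), "'set' must be a gene_set")
  .assert(dataset$scale == "log2",
          "gene-set scores are defined on log2 data; run to_log2() first")
  matched <- intersect(set$genes, rownames(dataset$values))
  if (length(matched) == 0) {
    stop("gene set '", set$name, "' has no genes in the dataset", call. = FALSE)
  }
  coverage <- length(matched) / length(set$genes)
  if (coverage < 1) {
    .log(sprintf("gene_set_score('%s'): %d/%d genes missing from dataset",
                 set$name, length(set$genes) - length(matched),
                 length(set$genes)), verbose = verbose)
  }
  if (coverage < 0.5) {
    warning(sprintf("gene set '%s': coverage %.0f%% is below 50%%; scores may not be interpretable",
                    set$name, 100 * coverage), call. = FALSE)
  }
  score <- colMeans(dataset$values[matched, , drop = FALSE])
  structure(score, gene_set = set$name, matched_genes = matched,
            coverage = coverage, standardized = FALSE, cohort = NULL,
            class = "score_vector")
}

#' Mean-center and scale a score vector
#'
#' `(score - mean) / sd` with the sd computed over the scored cohort using
#' denominator `n - 1`. Standardized scores are cohort-dependent by
#' construction, so the cohort identity is recorded on the result.
#'
#' @param score A `score_vector` (or plain named numeric vector).
#' @param cohort Label recording which cohort defined the standardization;
#'   defaults to `"all_scored_samples(n=<n>)"`.
#' @return A standardized `score_vector` (mean 0, sd 1).
#' @export
standardize_scores <- function(score, cohort = NULL) {
  x <- as.numeric(score)
  .assert(length(x) >= 2, "standardization needs >= 2 samples")
  s <- stats::sd(x)
  .assert(is.finite(s) && s > 0,
          "score variance is zero; standardized scores are undefined")
  out <- (x - mean(x)) / s
  names(out) <- names(score)
  structure(out,
            gene_set = attr(score, "gene_set"),
            matched_genes = attr(score, "matched_genes"),
            coverage = attr(score, "coverage"),
            standardized = TRUE,
            cohort = cohort %||% sprintf("all_scored_samples(n=%d)", length(x)),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector '%s': %d samples, coverage %.0f%%%s\n",
              attr(x, "gene_set") %||% "?", length(x),
              100 * (attr(x, "coverage") %||% NA_real_),
              if (isTRUE(attr(x, "standardized")))
                sprintf(" [standardized over %s]", attr(x, "cohort")) else ""))
  print(utils::head(stats::setNames(as.numeric(x), names(x))))
  invisible(x)
}

#' Score a panel of gene sets
#'
#' Applies [gene_set_score()] per set and returns a long-format table. A
#' failing set (e.g. empty intersection) becomes a failure record and does
#' not stop the other sets.
#'
#' @param dataset A log2-scale [expression_dataset()].
#' @param collection A [gene_set_collection()].
#' @param standardize Also standardize each set's scores over all samples.
#' @param verbose Passed through to [gene_set_score()].
#' @return A data.frame with columns `sample_id`, `gene_set`, `score`,
#'   `coverage`, `standardized`; failure records are in
#'   `attr(, "failures")` (columns `gene_set`, `error`).
#' @export
score_panel <- function(dataset, collection, standardize = FALSE,
                        verbose = TRUE) {
  .assert(inherits(collection, "gene_set_collection"),
          "'collection' must be a gene_set_collection")
  rows <- list()
  failures <- data.frame(gene_set = character(0), error = character(0),
                         stringsAsFactors = FALSE)
  for (set in collection) {
    sv <- tryCatch(gene_set_score(dataset, set, verbose = verbose),
                   error = function(e) e)
    if (inherits(sv, "error")) {
      failures <- rbind(failures,
                        data.frame(gene_set = set$name,
                                   error = conditionMessage(sv),
                                   stringsAsFactors = FALSE))
      next
    }
    if (standardize) sv <- standardize_scores(sv)
    rows[[set$name]] <- data.frame(sample_id = names(sv),
                                   gene_set = set$name,
                                   score = as.numeric(sv),
                                   coverage = attr(sv, "coverage"),
                                   standardized = isTRUE(attr(sv, "standardized")),
                                   stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(sample_id = character(0), gene_set = character(0),
                         score = numeric(0), coverage = numeric(0),
                         standardized = logical(0), stringsAsFactors = FALSE)
  attr(out, "failures") <- failures
  out
}

#' Write a long-format score table as TSV
#' @param score_table Result of [score_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(score_table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(names(score_table), collapse = "\t")
  body <- do.call(paste, c(lapply(score_table, function(x) {
    if (is.numeric(x)) .format_full(x) else as.character(x)
  }), sep = "\t"))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
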