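#' Expression dataset container
#'
#' Holds a genes x samples expression matrix together with its measurement
#' scale and per-sample metadata. Genes are rows and samples are columns
#' everywhere in this package; no function transposes implicitly.
#'
#' @param values Numeric matrix, rows = genes, columns = samples.
#' @param gene_ids Character vector of unique row identifiers. Defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of unique column identifiers. Defaults
#'   to `colnames(values)`.
#' @param scale Either `"linear"` (non-negative intensities/counts) or
#'   `"log2"`.
#' @param pseudocount Pseudocount recorded for log2-scaled data (`NA` when
#'   unknown, e.g. data already delivered on the log2 scale). Ignored for
#'   linear data.
#' @param metadata Optional data.frame of per-sample records with a mandatory
#'   `sample_id` column. Every `sample_id` must exist among `sample_ids`;
#'   extra rows are an error, never silently dropped. Rows are aligned to
#'   column order; samples without a record get `NA` fields.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values),
                               scale = c("linear", "log2"),
                               pseudocount = NA_real_,
                               metadata = NULL) {
  scale <- match.arg(scale)
  .assert(is.matrix(values) && is.numeric(values),
          "'values' must be a numeric matrix (genes x samples)")
  .assert(!is.null(gene_ids) && length(gene_ids) == nrow(values),
          "gene_ids must match the number of rows")
  .assert(!is.null(sample_ids) && length(sample_ids) == ncol(values),
          "sample_ids must match the number of columns")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  .assert(length(dup_g) == 0,
          "duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  .assert(length(dup_s) == 0,
          "duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (scale == "linear") {
    .assert(all(values >= 0, na.rm = TRUE),
            "linear-scale values must be non-negative")
    pseudocount <- NA_real_
  }
  dimnames(values) <- list(gene_ids, sample_ids)

  metadata <- .align_metadata(metadata, sample_ids)

  structure(
    list(values = values, scale = scale, pseudocount = pseudocount,
         metadata = metadata),
    class = "expression_dataset"
  )
}

# Align a metadata data.frame to sample order; unknown sample ids are an
# error (extra metadata rows must not vanish silently).
.align_metadata <- function(metadata, sample_ids) {
  if (is.null(metadata)) {
    return(data.frame(sample_id = sample_ids, stringsAsFactors = FALSE))
  }
  .assert(is.data.frame(metadata), "metadata must be a data.frame")
  .assert("sample_id" %in% names(metadata),
          "metadata must contain a 'sample_id' column")
  metadata$sample_id <- as.character(metadata$sample_id)
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  .assert(length(dup) == 0,
          "duplicate metadata rows for sample(s): ", paste(dup, collapse = ", "))
  unknown <- setdiff(metadata$sample_id, sample_ids)
  .assert(length(unknown) == 0,
          "metadata rows for unknown sample(s): ", paste(unknown, collapse = ", "))
  idx <- match(sample_ids, metadata$sample_id)
  out <- metadata[idx, , drop = FALSE]
  out$sample_id <- sample_ids
  rownames(out) <- NULL
  out
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Gene and sample identifiers
#' @param x An `expression_dataset`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples [%s scale%s]\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$scale == "log2" && !is.na(x$pseudocount))
                sprintf(", pseudocount %g", x$pseudocount) else ""))
  extra <- setdiff(names(x$metadata), "sample_id")
  if (length(extra)) {
    cat("metadata fields:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

.infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "txt", "tab")) return("\t")
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited expression matrix
#'
#' First column holds gene ids, header row holds sample ids. The delimiter is
#' inferred from the file extension (`.csv` vs `.tsv`/`.txt`) or the first
#' line, unless given.
#'
#' @param path File path.
#' @param sep Optional field delimiter; inferred when `NULL`.
#' @param scale Scale to record; files are assumed linear unless the caller
#'   asserts `"log2"`.
#' @param pseudocount Pseudocount to record when asserting log2 data.
#' @param metadata Optional metadata data.frame (see [expression_dataset()]).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, sep = NULL, scale = c("linear", "log2"),
                            pseudocount = NA_real_, metadata = NULL) {
  scale <- match.arg(scale)
  .assert(file.exists(path), "file not found: ", path)
  sep <- .infer_sep(path, sep)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "", fill = FALSE,
                           stringsAsFactors = FALSE)
  .assert(ncol(tab) >= 2, "expression table needs a gene-id column plus >= 1 sample")
  genes <- tab[[1L]]
  dup <- unique(genes[duplicated(genes)])
  .assert(length(dup) == 0,
          "duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  samples <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples))
  for (j in seq_along(samples)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(col %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                   genes[bad[1L]], samples[j], col[bad[1L]]), call. = FALSE)
    }
    vals[, j] <- num
  }
  expression_dataset(vals, gene_ids = genes, sample_ids = samples,
                     scale = scale, pseudocount = pseudocount,
                     metadata = metadata)
}

#' Write an expression matrix as a delimited text file
#'
#' Values are written at full precision (`%.17g`) so a write/read round trip
#' reproduces the matrix bit-exactly. UTF-8, LF line endings.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path; delimiter inferred from extension unless `sep`
#'   given.
#' @param sep Optional delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, sep = NULL) {
  sep <- if (is.null(sep)) {
    if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  } else sep
  header <- paste(c("gene_id", colnames(dataset$values)), collapse = sep)
  body <- vapply(seq_len(nrow(dataset$values)), function(i) {
    paste(c(rownames(dataset$values)[i], .format_full(dataset$values[i, ])),
          collapse = sep)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Delimited table with a mandatory `sample_id` column. Empty strings and
#' `"NA"` become missing values.
#'
#' @param path File path.
#' @param sep Optional delimiter; inferred when `NULL`.
#' @return A data.frame.
#' @export
read_metadata <- function(path, sep = NULL) {
  .assert(file.exists(path), "file not found: ", path)
  sep <- .infer_sep(path, sep)
  md <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "", fill = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  .assert("sample_id" %in% names(md), "metadata must contain 'sample_id'")
  md$sample_id <- as.character(md$sample_id)
  md
}

#' Write a metadata table
#' @param metadata A data.frame with a `sample_id` column.
#' @param path Output path.
#' @param sep Optional delimiter.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path, sep = NULL) {
  sep <- if (is.null(sep)) {
    if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  } else sep
  fields <- names(metadata)
  fmt_cell <- function(x) {
    if (is.numeric(x)) .format_full(x) else {
      out <- as.character(x); out[is.na(out)] <- "NA"; out
    }
  }
  cols <- lapply(metadata, fmt_cell)
  body <- do.call(paste, c(cols, sep = sep))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(fields, collapse = sep), body), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Filter samples by metadata predicates
#'
#' Keeps exactly the samples satisfying all clauses (a conjunction).
#' Clauses are a named list: a scalar or vector means set membership for the
#' field, a function is applied to the field and must return logical, and a
#' list with `min`/`max` bounds a numeric field (inclusive). Missing values
#' never satisfy a clause.
#'
#' @param dataset An [expression_dataset()].
#' @param predicate Named list of clauses; `list()` keeps everything.
#' @param verbose Log before/after counts to stderr.
#' @return A new `expression_dataset`; the input is untouched.
#' @export
filter_samples <- function(dataset, predicate = list(), verbose = TRUE) {
  md <- dataset$metadata
  keep <- rep(TRUE, ncol(dataset$values))
  for (field in names(predicate)) {
    .assert(field %in% names(md),
            "unknown metadata field '", field, "'; available: ",
            paste(setdiff(names(md), "sample_id"), collapse = ", "))
    clause <- predicate[[field]]
    col <- md[[field]]
    ok <- if (is.function(clause)) {
      isTRUE_v <- clause(col)
      .assert(is.logical(isTRUE_v) && length(isTRUE_v) == length(col),
              "predicate function for '", field, "' must return logical per sample")
      isTRUE_v
    } else if (is.list(clause)) {
      v <- rep(TRUE, length(col))
      if (!is.null(clause$min)) v <- v & (col >= clause$min)
      if (!is.null(clause$max)) v <- v & (col <= clause$max)
      v
    } else {
      col %in% clause
    }
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  .log(sprintf("filter_samples: %d -> %d samples", length(keep), sum(keep)),
       verbose = verbose)
  expression_dataset(dataset$values[, keep, drop = FALSE],
                     scale = dataset$scale,
                     pseudocount = dataset$pseudocount,
                     metadata = md[keep, , drop = FALSE])
}

#' Log2-transform a linear-scale dataset
#'
#' `log2(value + pseudocount)`, recording the pseudocount. Applying this to a
#' dataset already on the log2 scale is an error: no silent double transform.
#'
#' @param dataset An [expression_dataset()] with `scale = "linear"`.
#' @param pseudocount Positive pseudocount (default 1).
#' @return A log2-scale `expression_dataset`.
#' @export
to_log2 <- function(dataset, pseudocount = 1) {
  .assert(inherits(dataset, "expression_dataset"), "not an expression_dataset")
  .assert(dataset$scale == "linear",
          "dataset is already log2-scaled; refusing a double transform")
  .assert(is.numeric(pseudocount) && pseudocount > 0, "pseudocount must be > 0")
  .assert(all(dataset$values >= 0, na.rm = TRUE), "negative input values")
  expression_dataset(log2(dataset$values + pseudocount),
                     scale = "log2", pseudocount = pseudocount,
                     metadata = dataset$metadata)
}
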