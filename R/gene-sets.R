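#' Gene sets and collections
#'
#' A `gene_set` is a named, duplicate-free list of gene identifiers with a
#' free-text source label. A `gene_set_collection` is an ordered, uniquely
#' named map of gene sets. Gene identifiers match dataset rows by exact,
#' case-sensitive string equality; no alias mapping is attempted.
#'
#' @param name Set name.
#' @param genes Character vector of gene ids (non-empty; duplicates removed
#'   with a warning).
#' @param source Free-text provenance label.
#' @return A `gene_set`.
#' @export
gene_set <- function(name, genes, source = "") {
  .assert(is.character(name) && length(name) == 1 && nzchar(name),
          "gene set needs a non-empty name")
  genes <- as.character(genes)
  .assert(length(genes) >= 1, "gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': removed %d duplicate gene id(s)",
                    name, sum(duplicated(genes))), call. = FALSE)
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, source = source),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d genes%s)\n", x$name, length(x$genes),
              if (nzchar(x$source)) paste0("; source: ", x$source) else ""))
  invisible(x)
}

#' @rdname gene_set
#' @param sets List of `gene_set` objects.
#' @return A `gene_set_collection` (ordered named list).
#' @export
gene_set_collection <- function(sets) {
  .assert(length(sets) >= 0 && all(vapply(sets, inherits, TRUE, "gene_set")),
          "all elements must be gene_set objects")
  nms <- vapply(sets, `[[`, character(1), "name")
  dup <- unique(nms[duplicated(nms)])
  .assert(length(dup) == 0,
          "duplicate gene set names: ", paste(dup, collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d set(s)\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-24s %4d genes\n", s$name, length(s$genes)))
  }
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i])
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description is retained
#' as the set's source label. Within-set duplicate genes are removed with a
#' warning. An empty file yields an empty collection.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    sets[[i]] <- gene_set(fields[1L], fields[-(1:2)], source = fields[2L])
  }
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    paste(c(s$name, if (nzchar(s$source)) s$source else ".", s$genes),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
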