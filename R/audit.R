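# End-to-end "specificity audit" pipeline: score a panel of signatures on a
# cohort, measure purity correlation, compartment contrasts and paired
# retention, and emit a tumor-intrinsic verdict per signature.

#' Run a signature specificity audit
#'
#' Executes filter -> log2 (if needed) -> score -> purity correlation ->
#' compartment panel -> paired retention -> optional gene-based
#' decomposition -> verdicts. The cohort either comes from files named in
#' the config or from the synthetic generator (a `simulate` block). Every
#' stage outcome is recorded in a manifest; all randomness is governed by
#' the config's mandatory `seed` (no wall-clock seeding), so a rerun with
#' the same config is byte-identical.
#'
#' @param config A named list, or a path to a YAML/JSON config file, with
#'   fields:
#'   \describe{
#'     \item{seed}{mandatory integer seed.}
#'     \item{simulate}{optional named list of [simulation_config()]
#'       overrides; mutually exclusive with `data`.}
#'     \item{data}{optional list with paths `expression`, `metadata`,
#'       `gene_sets`, plus `scale` (`"linear"`/`"log2"`) and `pseudocount`.}
#'     \item{filter}{optional predicate list for [filter_samples()].}
#'     \item{purity_tissue}{tissue type used for the purity correlation
#'       (default `"primary_tumor"`).}
#'     \item{contrasts}{list of tissue-type pairs for [compartment_panel()]
#'       (default primary vs cell line, primary vs caf).}
#'     \item{retention}{list with `source` and `derived` tissue types
#'       (default primary -> cell line).}
#'     \item{decompose}{optional list with `set`, `k` and optionally
#'       `resamples` for [decompose_signature()].}
#'     \item{rules}{optional [verdict_rules()] overrides
#'       (`rho_threshold`, `p_threshold`).}
#'   }
#' @param out_dir Optional directory for the report bundle (JSON report,
#'   TSV tables, config echo, MANIFEST). `NULL` skips writing.
#' @param verbose Log stage progress to stderr.
#' @return A `sig_audit` object: list with `config`, `scores`, `purity`,
#'   `contrasts`, `retention`, `decomposition`, `verdicts`, `manifest`,
#'   `success`.
#' @export
run_audit <- function(config, out_dir = NULL, verbose = TRUE) {
  if (is.character(config) && length(config) == 1) {
    .assert(file.exists(config), "config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  .assert(is.list(config), "config must be a list or a YAML/JSON path")
  .assert(!is.null(config$seed), "config must set a seed (no wall-clock seeding)")

  manifest <- list()
  note <- function(stage, status, detail = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, status = status, detail = detail,
      stringsAsFactors = FALSE)
    .log(sprintf("[%s] %s %s", stage, status, detail), verbose = verbose)
  }
  run_stage <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      note(stage, "FAILED", conditionMessage(out))
      NULL
    } else {
      out
    }
  }

  # --- input stage -------------------------------------------------------
  truth <- NULL
  inputs <- run_stage("load", {
    if (!is.null(config$simulate)) {
      sim_block <- if (is.list(config$simulate)) config$simulate else list()
      sim_cfg <- do.call(simulation_config,
                         c(sim_block,
                           if (is.null(sim_block$seed))
                             list(seed = config$seed)))
      cohort <- generate_cohort(sim_cfg)
      truth <- cohort$truth
      note("load", "OK", sprintf("simulated cohort: %d samples",
                                 ncol(cohort$dataset$values)))
      list(dataset = cohort$dataset, sets = cohort$gene_sets, truth = truth)
    } else {
      .assert(!is.null(config$data),
              "config needs either a 'simulate' or a 'data' block")
      for (f in c("expression", "metadata", "gene_sets")) {
        .assert(!is.null(config$data[[f]]), "data block lacks '", f, "'")
        .assert(file.exists(config$data[[f]]),
                "file not found: ", config$data[[f]])
      }
      md <- read_metadata(config$data$metadata)
      ds <- read_expression(config$data$expression,
                            scale = config$data$scale %||% "linear",
                            pseudocount = config$data$pseudocount %||% NA_real_,
                            metadata = md)
      note("load", "OK", sprintf("%d genes x %d samples", nrow(ds$values),
                                 ncol(ds$values)))
      list(dataset = ds, sets = read_gmt(config$data$gene_sets), truth = NULL)
    }
  })
  if (is.null(inputs)) {
    manifest_df <- do.call(rbind, c(manifest, make.row.names = FALSE))
    return(.audit_finish(NULL, config, manifest_df, out_dir, success = FALSE,
                         verbose = verbose))
  }
  dataset <- inputs$dataset
  sets <- inputs$sets

  if (!is.null(config$filter)) {
    dataset <- run_stage("filter", {
      out <- filter_samples(dataset, config$filter, verbose = verbose)
      note("filter", "OK", sprintf("%d samples retained", ncol(out$values)))
      out
    }) %||% dataset
  }
  if (dataset$scale == "linear") {
    dataset <- run_stage("to_log2", {
      out <- to_log2(dataset, pseudocount = config$pseudocount %||% 1)
      note("to_log2", "OK", "")
      out
    }) %||% dataset
  }

  # --- scoring -----------------------------------------------------------
  scores <- run_stage("score", {
    out <- score_panel(dataset, sets, standardize = FALSE, verbose = FALSE)
    fails <- attr(out, "failures")
    note("score", if (nrow(fails)) "PARTIAL" else "OK",
         sprintf("%d sets scored, %d failed",
                 length(unique(out$gene_set)), nrow(fails)))
    out
  })

  md <- dataset$metadata
  purity_tissue <- config$purity_tissue %||% "primary_tumor"
  contrasts <- config$contrasts %||% list(c("primary_tumor", "cell_line"),
                                          c("primary_tumor", "caf"))
  contrasts <- lapply(contrasts, as.character)
  retention_cfg <- config$retention %||% list(source = "primary_tumor",
                                              derived = "cell_line")
  rules <- do.call(verdict_rules, as.list(config$rules %||% list()))

  set_names <- unique(scores$gene_set)
  score_vectors <- lapply(stats::setNames(set_names, set_names), function(s) {
    gene_set_score(dataset, sets[[s]], verbose = FALSE)
  })

  # --- purity correlation (within the purity tissue type) ----------------
  purity <- run_stage("purity_correlation", {
    keep <- md$sample_id[md$tissue_type %in% purity_tissue]
    out <- lapply(score_vectors, function(sv) {
      tryCatch(purity_correlation(sv[names(sv) %in% keep], md),
               error = function(e) list(rho = NA_real_, p = NA_real_,
                                        n_used = 0L,
                                        error = conditionMessage(e)))
    })
    note("purity_correlation", "OK", sprintf("%d sets", length(out)))
    out
  })

  # --- compartment contrasts --------------------------------------------
  contrast_tab <- run_stage("compartment_panel", {
    out <- compartment_panel(scores, md, contrasts)
    note("compartment_panel", "OK", sprintf("%d rows", nrow(out)))
    out
  })

  # --- paired retention --------------------------------------------------
  retention <- run_stage("paired_retention", {
    out <- lapply(score_vectors, function(sv) {
      tryCatch(paired_retention(sv, md,
                                source_type = retention_cfg$source,
                                derived_type = retention_cfg$derived),
               error = function(e) list(rho = NA_real_, p = NA_real_,
                                        n_pairs = 0L, loss = NA_real_,
                                        error = conditionMessage(e)))
    })
    note("paired_retention", "OK", sprintf("%d sets", length(out)))
    out
  })

  # --- optional gene-based decomposition ---------------------------------
  decomposition <- NULL
  if (!is.null(config$decompose)) {
    decomposition <- run_stage("decompose", {
      dc <- config$decompose
      out <- decompose_signature(dataset, sets[[dc$set]], k = dc$k,
                                 resamples = dc$resamples %||% 250,
                                 seed = config$seed)
      note("decompose", "OK", sprintf("set '%s' into %d clusters", dc$set, dc$k))
      out
    })
  }

  # --- verdicts ----------------------------------------------------------
  verdicts <- run_stage("verdicts", {
    out <- lapply(stats::setNames(set_names, set_names), function(s) {
      ctr <- NULL
      if (!is.null(contrast_tab)) {
        row <- contrast_tab[contrast_tab$gene_set == s &
                              contrast_tab$group_a %in% retention_cfg$source &
                              contrast_tab$group_b %in% retention_cfg$derived, ,
                            drop = FALSE]
        if (nrow(row) == 1) {
          ctr <- list(mean_primary = row$mean_a, mean_derived = row$mean_b,
                      p = row$p)
        }
      }
      fragment <- list(purity_rho = purity[[s]]$rho,
                       purity_p = purity[[s]]$p,
                       contrast = ctr,
                       paired_loss = retention[[s]]$loss)
      signature_verdict(fragment, rules)
    })
    note("verdicts", "OK",
         paste(vapply(names(out), function(s) {
           paste0(s, "=", out[[s]]$verdict)
         }, character(1)), collapse = " "))
    out
  })

  manifest_df <- do.call(rbind, c(manifest, make.row.names = FALSE))
  success <- !any(manifest_df$status == "FAILED")
  audit <- structure(
    list(config = config, truth = inputs$truth, scores = scores,
         purity = purity, contrasts = contrast_tab, retention = retention,
         decomposition = decomposition, verdicts = verdicts,
         manifest = manifest_df, success = success),
    class = "sig_audit")
  .audit_finish(audit, config, manifest_df, out_dir, success,
                verbose = verbose)
}

.audit_finish <- function(audit, config, manifest, out_dir, success,
                          verbose = TRUE) {
  if (is.null(audit)) {
    audit <- structure(list(config = config, manifest = manifest,
                            success = FALSE), class = "sig_audit")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      config = config,
      purity = audit$purity,
      retention = lapply(audit$retention, function(r) r[setdiff(names(r), "pairs")]),
      verdicts = lapply(audit$verdicts, function(v) {
        list(verdict = v$verdict, rules_fired = as.list(v$rules_fired),
             rules = unclass(v$rules))
      }),
      success = audit$success)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (!is.null(audit$scores)) {
      write_score_table(audit$scores, file.path(out_dir, "scores.tsv"))
    }
    if (!is.null(audit$contrasts)) {
      utils::write.table(audit$contrasts, file.path(out_dir, "contrasts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(audit$verdicts)) {
      vt <- data.frame(gene_set = names(audit$verdicts),
                       verdict = vapply(audit$verdicts, `[[`, character(1),
                                        "verdict"),
                       rules_fired = vapply(audit$verdicts, function(v) {
                         paste(v$rules_fired, collapse = ";")
                       }, character(1)),
                       stringsAsFactors = FALSE)
      utils::write.table(vt, file.path(out_dir, "verdicts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(config, file.path(out_dir, "config_echo.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man <- if (is.data.frame(manifest)) manifest
           else do.call(rbind, c(manifest, make.row.names = FALSE))
    utils::write.table(man, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log("bundle written to ", out_dir, verbose = verbose)
  }
  audit
}

#' @export
print.sig_audit <- function(x, ...) {
  cat(sprintf("sig_audit (%s)\n", if (x$success) "complete" else "FAILED"))
  if (!is.null(x$verdicts)) {
    for (s in names(x$verdicts)) {
      pr <- x$purity[[s]]
      cat(sprintf("  %-18s %-15s rho=%+.3f p=%.3g loss=%+.3f\n", s,
                  x$verdicts[[s]]$verdict, pr$rho, pr$p,
                  x$retention[[s]]$loss))
    }
  }
  invisible(x)
}

#' @export
summary.sig_audit <- function(object, ...) {
  print(object)
  cat("\nstage manifest:\n")
  print(object$manifest)
  invisible(object)
}

#' Export a reordered expression matrix for external heatmapping
#'
#' Rows/columns are permuted according to order specs: a character vector of
#' ids (explicit order), a named numeric vector (ascending sort, ties broken
#' by id), or a named character/factor vector of group assignments
#' (contiguous blocks in level order, ids sorted within a block). Values are
#' exported unchanged.
#'
#' @param dataset An [expression_dataset()].
#' @param row_order,col_order Order specs (or `NULL` to keep current order).
#' @param path Optional TSV output path; a JSON sidecar `<path>.orders.json`
#'   records both orderings.
#' @return The reordered matrix, invisibly when writing.
#' @export
export_ordered_matrix <- function(dataset, row_order = NULL, col_order = NULL,
                                  path = NULL) {
  resolve <- function(spec, ids, what) {
    if (is.null(spec)) return(ids)
    if (is.character(spec) && is.null(names(spec))) {
      missing <- setdiff(spec, ids)
      .assert(length(missing) == 0, what, " order references unknown ids: ",
              paste(missing, collapse = ", "))
      return(spec)
    }
    .assert(!is.null(names(spec)), what,
            " order spec must be named by id (or be an id vector)")
    unknown <- setdiff(names(spec), ids)
    .assert(length(unknown) == 0, what, " order references unknown ids: ",
            paste(unknown, collapse = ", "))
    spec <- spec[intersect(ids, names(spec))]
    if (is.numeric(spec)) {
      names(spec)[order(spec, names(spec))]
    } else {
      f <- if (is.factor(spec)) spec else factor(as.character(spec))
      names(spec)[order(f, names(spec))]
    }
  }
  rows <- resolve(row_order, rownames(dataset$values), "row")
  cols <- resolve(col_order, colnames(dataset$values), "column")
  out <- dataset$values[rows, cols, drop = FALSE]
  if (!is.null(path)) {
    ds_out <- expression_dataset(out, scale = dataset$scale,
                                 pseudocount = dataset$pseudocount)
    write_expression(ds_out, path)
    jsonlite::write_json(list(rows = rows, columns = cols),
                         paste0(path, ".orders.json"), auto_unbox = FALSE)
    return(invisible(out))
  }
  out
}
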