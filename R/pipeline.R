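#' Read a pipeline configuration file
#'
#' Flat YAML keys; command-line flags are expected to override file values
#' (the CLI does this). Unknown keys are kept and passed through.
#'
#' @param path YAML file.
#' @return named list of class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of keys to values")
  structure(cfg, class = c("PipelineConfig", "list"))
}

pipeline_log <- function(lines, out_dir) {
  path <- file.path(out_dir, "run.log")
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), lines, "\n"),
      file = path, append = TRUE, sep = "")
  invisible(path)
}

input_checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
}

#' Run the RNA-seq screen end to end
#'
#' Reads counts, annotation, candidate list and (optionally) an external
#' L2FC table, runs [screen_candidates()] and writes `ranking.tsv`,
#' `summary.json` and `run.log` under `out_dir`.
#'
#' @param counts path to the count table.
#' @param annotation path to the sample annotation.
#' @param candidates candidate list (path or `"builtin:..."` name).
#' @param out_dir output directory.
#' @param l2fc optional path to an external L2FC TSV; when `NULL` the naive
#'   estimate is used unless `no_naive_l2fc` is set.
#' @param exclusion optional exclusion list (path or builtin name).
#' @param dialect count-table dialect, see [read_counts()].
#' @param tpm_mode `"standard"` or `"literal"`.
#' @param cv_threshold,top_k screen parameters, see [screen_config()].
#' @param no_naive_l2fc fail rather than fall back to the naive L2FC.
#' @param test,control condition labels.
#' @return invisibly, the [screen_candidates()] result.
#' @export
run_screen <- function(counts, annotation, candidates, out_dir,
                       l2fc = NULL, exclusion = NULL,
                       dialect = "plain-tsv", tpm_mode = "standard",
                       cv_threshold = 0.15, top_k = 4,
                       no_naive_l2fc = FALSE, test = "Hx", control = "Nx") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  x <- read_counts(counts, dialect = dialect)
  ann <- read_sample_annotation(annotation, test = test, control = control)
  cand <- load_gene_list(candidates)
  l2fc_tab <- if (!is.null(l2fc)) read_l2fc_table(l2fc) else NULL
  if (is.null(l2fc_tab) && no_naive_l2fc) {
    stop("no external L2FC table supplied and the naive fallback is disabled")
  }
  excl <- if (!is.null(exclusion)) load_gene_list(exclusion) else NULL
  cfg <- screen_config(cv_threshold = cv_threshold, top_k = top_k)
  res <- screen_candidates(x, ann, cand, l2fc = l2fc_tab, exclusion = excl,
                           config = cfg, tpm_mode = tpm_mode)
  write_tsv_report(res$ranking, file.path(out_dir, "ranking.tsv"))
  summary <- list(
    schema_version = "1.0",
    tool = paste0("hkgselect ", as.character(utils::packageVersion("hkgselect"))),
    top_k = res$shortlist,
    n_candidates = nrow(res$cv_summary),
    n_eligible = nrow(res$ranking),
    l2fc_source = res$l2fc_source,
    cv_threshold = cv_threshold,
    inputs = as.list(input_checksums(list(counts = counts,
                                          annotation = annotation))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(c(sprintf("screen: %d candidates, %d eligible, shortlist = %s",
                         summary$n_candidates, summary$n_eligible,
                         paste(res$shortlist, collapse = ","))), out_dir)
  invisible(res)
}

#' Run the qRT-PCR stability validation end to end
#'
#' Reads a long-format Ct table, preprocesses it at the detection limit and
#' runs [combined_ranking()], writing `stability_overall.tsv`,
#' `stability_by_line.tsv`, `summary.json` and `run.log` under `out_dir`.
#'
#' @param ct path to the Ct CSV.
#' @param out_dir output directory.
#' @param lod detection limit (default 35).
#' @param test,control condition labels.
#' @param variant per-line final rank variant, see [combined_ranking()].
#' @return invisibly, the `StabilityReport`.
#' @export
run_validate <- function(ct, out_dir, lod = 35, test = "Hx", control = "Nx",
                         variant = "six_method") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_ct_table(ct)
  m <- preprocess_ct(tab, lod = lod)
  report <- combined_ranking(m, test = test, ctrl = control, variant = variant)
  single_line <- length(report$per_line) < 2
  by_line <- do.call(rbind, lapply(names(report$per_line), function(cl) {
    cbind(cell_line = cl, report$per_line[[cl]])
  }))
  write_tsv_report(by_line, file.path(out_dir, "stability_by_line.tsv"))
  overall <- report$overall
  if (single_line) overall$note <- "insufficient lines for overall averaging"
  write_tsv_report(overall, file.path(out_dir, "stability_overall.tsv"))
  summary <- list(
    schema_version = "1.0",
    tool = paste0("hkgselect ", as.character(utils::packageVersion("hkgselect"))),
    lod = lod, variant = variant,
    n_lines = length(report$per_line),
    overall_order = report$overall$gene,
    notes = report$notes,
    qc = m$qc$message,
    dropped = if (nrow(m$dropped)) paste(m$dropped$gene, m$dropped$cell_line) else character(),
    inputs = as.list(input_checksums(list(ct = ct))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(c(sprintf("validate: %d lines, overall order = %s",
                         length(report$per_line),
                         paste(report$overall$gene, collapse = ","))), out_dir)
  invisible(report)
}

#' Fold-change query on a Ct table
#'
#' Convenience wrapper: read, preprocess and run [livak_fold()].
#'
#' @param ct path to the Ct CSV.
#' @param target target gene.
#' @param references character vector of reference genes.
#' @param lod detection limit.
#' @param test,control condition labels.
#' @return a `FoldResult`.
#' @export
run_fold <- function(ct, target, references, lod = 35,
                     test = "Hx", control = "Nx") {
  m <- preprocess_ct(read_ct_table(ct), lod = lod)
  livak_fold(m, target, references, test = test, ctrl = control)
}
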