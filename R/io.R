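#' Construct an expression matrix
#'
#' Container for gene-level raw counts: a genes x samples matrix with gene
#' identifiers, display symbols and (optionally) gene lengths in base pairs.
#' Lengths are only required once TPM normalization is requested.
#'
#' @param counts numeric matrix, genes x samples, non-negative.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param sample_ids character vector of unique sample identifiers (columns).
#' @param gene_symbols display symbols; defaults to `gene_ids`.
#' @param lengths optional positive gene lengths (bp), same order as rows.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              sample_ids = colnames(counts),
                              gene_symbols = gene_ids, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  }
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(sample_ids)) {
    stop("counts dimensions do not match gene/sample identifiers")
  }
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (!is.null(lengths)) {
    lengths <- as.numeric(lengths)
    if (length(lengths) != nrow(counts)) stop("lengths do not match genes")
    if (any(!is.finite(lengths)) || any(lengths <= 0)) {
      stop("gene lengths must be positive")
    }
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids,
         gene_symbols = as.character(gene_symbols), lengths = lengths),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s lengths)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$lengths)) "no" else "with"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a gene-level count table
#'
#' Two dialects are supported. `plain-tsv`: a header row of sample IDs and a
#' first column of gene IDs. `featurecounts`: the output of featureCounts,
#' whose leading `#`-comment line is skipped, `Geneid` becomes the gene ID,
#' `Length` the gene length, and the `Chr`/`Start`/`End`/`Strand` columns are
#' dropped.
#'
#' @param path file path.
#' @param dialect `"plain-tsv"` or `"featurecounts"`.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, dialect = c("plain-tsv", "featurecounts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "featurecounts") {
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!"Geneid" %in% names(df)) stop("featurecounts dialect requires a Geneid column")
    if (!"Length" %in% names(df)) stop("featurecounts dialect requires a Length column")
    ids <- as.character(df$Geneid)
    lengths <- df$Length
    drop <- intersect(c("Geneid", "Chr", "Start", "End", "Strand", "Length"),
                      names(df))
    counts <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
    rownames(counts) <- ids
    expression_matrix(counts, gene_ids = ids, lengths = lengths)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- ids
    expression_matrix(counts, gene_ids = ids)
  }
}

#' Read a sample annotation table
#'
#' Expects CSV or TSV (sniffed from the header line) with columns
#' `sample_id`, `cell_line`, `condition`, `replicate`. Condition labels are
#' validated against the configured test/control level names.
#'
#' @param path file path.
#' @param test,control condition level names (defaults `"Hx"` / `"Nx"`).
#' @return A `data.frame` of class `SampleAnnotation` with attributes
#'   `test` and `control`.
#' @export
read_sample_annotation <- function(path, test = "Hx", control = "Nx") {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  sample_annotation(df, test = test, control = control)
}

#' Construct / validate a sample annotation
#'
#' @param df data.frame with columns sample_id, cell_line, condition, replicate.
#' @inheritParams read_sample_annotation
#' @return the validated annotation.
#' @export
sample_annotation <- function(df, test = "Hx", control = "Nx") {
  need <- c("sample_id", "cell_line", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no samples in annotation")
  df$sample_id <- as.character(df$sample_id)
  df$cell_line <- as.character(df$cell_line)
  df$condition <- as.character(df$condition)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in annotation: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$condition), c(test, control))
  if (length(bad)) {
    stop("unknown condition level(s): ", paste(bad, collapse = ", "),
         " (expected ", test, " or ", control, ")")
  }
  attr(df, "test") <- test
  attr(df, "control") <- control
  class(df) <- c("SampleAnnotation", "data.frame")
  df
}

#' Join annotation to an expression matrix's samples
#'
#' @param x ExpressionMatrix.
#' @param ann SampleAnnotation.
#' @return annotation reordered to the matrix's samples.
#' @keywords internal
match_annotation <- function(x, ann) {
  miss <- setdiff(colnames(x$counts), ann$sample_id)
  if (length(miss)) {
    stop("samples present in counts but not annotated: ",
         paste(miss, collapse = ", "))
  }
  out <- ann[match(colnames(x$counts), ann$sample_id), , drop = FALSE]
  attr(out, "test") <- attr(ann, "test")
  attr(out, "control") <- attr(ann, "control")
  class(out) <- class(ann)
  out
}

#' Read a long-format qRT-PCR Ct table
#'
#' Expects CSV with columns `gene`, `cell_line`, `condition`, `run`,
#' `tech_rep`, `ct`. The `ct` column accepts numbers or below-detection
#' tokens such as `">35"` or `"Undetermined"`; these are kept as records with
#' `below_detection = TRUE` and `ct = NA`, not as numbers.
#'
#' @param path file path.
#' @param bd_tokens regular expression(s) / tokens treated as below-detection.
#' @return A `data.frame` of class `CtTable` with columns gene, cell_line,
#'   condition, run, tech_rep, ct, below_detection.
#' @export
read_ct_table <- function(path, bd_tokens = c("^>\\s*[0-9.]+$", "^Undetermined$")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "cell_line", "condition", "run", "tech_rep", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table missing columns: ", paste(miss, collapse = ", "))
  raw <- trimws(as.character(df$ct))
  bd <- Reduce(`|`, lapply(bd_tokens, function(tok) grepl(tok, raw, ignore.case = TRUE)))
  ct <- suppressWarnings(as.numeric(raw))
  bad <- which(!bd & is.na(ct))
  if (length(bad)) {
    stop("non-numeric ct value at data row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(raw[bad]), collapse = ", "))
  }
  if (any(ct[!bd] <= 0, na.rm = TRUE)) stop("ct values must be > 0")
  out <- data.frame(gene = as.character(df$gene),
                    cell_line = as.character(df$cell_line),
                    condition = as.character(df$condition),
                    run = as.character(df$run),
                    tech_rep = as.integer(df$tech_rep),
                    ct = ifelse(bd, NA_real_, ct),
                    below_detection = bd,
                    stringsAsFactors = FALSE)
  key <- do.call(paste, c(out[c("gene", "cell_line", "condition", "run", "tech_rep")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (gene, cell_line, condition, run, tech_rep) rows at data row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  class(out) <- c("CtTable", "data.frame")
  out
}

#' Path to a bundled data file
#'
#' Bundled files: `"literature_hkg"` (literature-curated housekeeping gene
#' candidates), `"hypoxia_inducible"` (a representative synthetic stand-in
#' exclusion list of hypoxia-inducible genes) and `"qpcr_ct"` (the published
#' hADSC validation Ct table, 5 genes x 4 cell lines).
#'
#' @param name one of the names above.
#' @return a file path.
#' @export
builtin_file <- function(name = c("literature_hkg", "hypoxia_inducible", "qpcr_ct")) {
  name <- match.arg(name)
  fn <- switch(name,
               literature_hkg = "literature_hkg.txt",
               hypoxia_inducible = "hypoxia_inducible_synthetic.txt",
               qpcr_ct = "qpcr_ct_hadsc.csv")
  path <- system.file("extdata", fn, package = "hkgselect")
  if (!nzchar(path)) stop("bundled file not found: ", fn)
  path
}

#' Load a gene list (candidate or exclusion set)
#'
#' @param name_or_path `"builtin:literature_hkg"`, `"builtin:hypoxia_inducible"`,
#'   or a path to a one-symbol-per-line text file (`#` comments and blank
#'   lines skipped).
#' @return character vector of unique symbols with attribute `source`.
#' @export
load_gene_list <- function(name_or_path) {
  if (grepl("^builtin:", name_or_path)) {
    key <- sub("^builtin:", "", name_or_path)
    path <- builtin_file(key)
    src <- name_or_path
  } else {
    path <- name_or_path
    src <- path
    if (!file.exists(path)) stop("gene list file not found: ", path)
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("gene list is empty: ", path)
  syms <- unique(lines)
  attr(syms, "source") <- src
  syms
}

#' Write a data frame as TSV (single header row, 4-decimal floats)
#'
#' @param df data.frame.
#' @param path output path.
#' @param digits decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, digits = 4) {
  out <- df
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), NA, sprintf(paste0("%.", digits, "f"), v)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# case-insensitive symbol matching between a candidate list and a matrix;
# returns indices into the matrix symbols, reporting (not failing on)
# unmatched candidates
match_symbols <- function(candidates, symbols) {
  idx <- match(toupper(candidates), toupper(symbols))
  unmatched <- candidates[is.na(idx)]
  if (length(unmatched)) {
    warning("candidate gene(s) not found in matrix: ",
            paste(unmatched, collapse = ", "))
  }
  stats::setNames(idx, candidates)
}
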