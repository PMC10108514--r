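#' TPM normalization
#'
#' Transcripts per million. In `standard` mode the per-gene length-normalized
#' rate `count / (length/1000)` is rescaled so each sample (column) sums to
#' one million, i.e. the denominator is the sum of rates over genes. In
#' `literal` mode the rate is divided by the library size in millions
#' (total raw counts / 1e6), which reads the classic three-term formula
#' verbatim with "sequencing depth" taken as library size; columns then do
#' not generally sum to 1e6.
#'
#' @param x [expression_matrix()] with lengths present.
#' @param mode `"standard"` (default) or `"literal"`.
#' @return a `NormalizedMatrix`: list with `values`, `method = "tpm"`,
#'   `parameters`.
#' @export
tpm_normalize <- function(x, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$lengths)) stop("gene lengths are required for TPM")
  lib <- colSums(x$counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(x$counts)[lib == 0], collapse = ", "))
  rate <- x$counts / (x$lengths / 1000)
  values <- if (mode == "standard") {
    sweep(rate, 2, colSums(rate) / 1e6, "/")
  } else {
    sweep(rate, 2, lib / 1e6, "/")
  }
  normalized_matrix(values, x, "tpm", list(mode = mode))
}

#' Median-of-ratios (size factor) normalization
#'
#' The size factor of sample j is the median over reference genes of
#' `count_gj / geometric_mean_g(counts)`, the reference set being the genes
#' with all-positive counts and the median taken on the log scale (so an
#' even number of reference genes interpolates geometrically, as the
#' canonical estimator does). Values are counts divided by their sample's
#' size factor.
#'
#' @param x [expression_matrix()], at least two samples.
#' @return a `NormalizedMatrix` with `method = "size_factor"` and the
#'   factors in `parameters$size_factors`.
#' @export
size_factor_normalize <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$counts) < 2) stop("size-factor normalization needs >= 2 samples")
  ref <- rowSums(x$counts > 0) == ncol(x$counts)
  if (!any(ref)) {
    stop("no gene has positive counts in all samples; ",
         "pseudo-reference fallback is disabled")
  }
  loggeo <- rowMeans(log(x$counts[ref, , drop = FALSE]))
  sf <- apply(x$counts[ref, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
  values <- sweep(x$counts, 2, sf, "/")
  normalized_matrix(values, x, "size_factor", list(size_factors = sf))
}

normalized_matrix <- function(values, source, method, parameters) {
  structure(
    list(values = values, gene_ids = source$gene_ids,
         gene_symbols = source$gene_symbols, method = method,
         parameters = parameters),
    class = "NormalizedMatrix"
  )
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (%s): %d genes x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Naive log2 fold change between conditions
#'
#' Fallback when no externally produced (e.g. shrunken differential
#' expression) L2FC table is supplied:
#' `l2fc = log2((mean_test + pc) / (mean_control + pc))` on normalized values.
#'
#' @param norm `NormalizedMatrix`.
#' @param ann `SampleAnnotation` covering the matrix's samples.
#' @param pseudocount non-negative; default 0.5 keeps zero means finite.
#' @return data.frame of class `L2FCTable` with columns gene, l2fc and
#'   attribute `source = "naive"` (no adjusted p-values).
#' @export
naive_l2fc <- function(norm, ann, pseudocount = 0.5) {
  stopifnot(inherits(norm, "NormalizedMatrix"), pseudocount >= 0)
  test <- attr(ann, "test"); ctrl <- attr(ann, "control")
  ann <- ann[match(colnames(norm$values), ann$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotation does not cover all samples")
  t_idx <- which(ann$condition == test)
  c_idx <- which(ann$condition == ctrl)
  if (!length(t_idx) || !length(c_idx)) {
    stop("both conditions must have at least one sample")
  }
  mt <- rowMeans(norm$values[, t_idx, drop = FALSE])
  mc <- rowMeans(norm$values[, c_idx, drop = FALSE])
  out <- data.frame(gene = norm$gene_symbols,
                    l2fc = log2((mt + pseudocount) / (mc + pseudocount)),
                    stringsAsFactors = FALSE)
  attr(out, "source") <- "naive"
  class(out) <- c("L2FCTable", "data.frame")
  out
}

#' Read an external log2-fold-change table
#'
#' TSV with header columns `gene`, `l2fc` and optionally `adj_p` (e.g. an
#' exported shrunken differential-expression result).
#'
#' @param path file path.
#' @return data.frame of class `L2FCTable`, attribute `source = "external"`.
#' @export
read_l2fc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "l2fc") %in% names(df))) {
    stop("L2FC table requires columns gene and l2fc")
  }
  if ("adj_p" %in% names(df)) {
    if (any(df$adj_p < 0 | df$adj_p > 1, na.rm = TRUE)) {
      stop("adj_p must lie in [0, 1]")
    }
  }
  attr(df, "source") <- "external"
  class(df) <- c("L2FCTable", "data.frame")
  df
}

#' Convert a log2 fold change to a signed fold change
#'
#' Uses the negative-reciprocal convention common in qPCR reporting:
#' `2^l2fc` for `l2fc >= 0` and `-2^(-l2fc)` for `l2fc < 0`, so a halving is
#' reported as -2 rather than 0.5. Rounding is left to the caller.
#'
#' @param l2fc numeric vector of finite log2 fold changes.
#' @return signed fold changes; always `|fold| >= 1`.
#' @export
l2fc_to_fold <- function(l2fc) {
  if (any(!is.finite(l2fc))) stop("l2fc must be finite")
  ifelse(l2fc >= 0, 2^l2fc, -2^(-l2fc))
}

#' Remove genes with low total counts
#'
#' Drops genes whose count summed across samples is below `threshold`
#' (default 10, the usual pre-filter before differential expression).
#'
#' @param x [expression_matrix()].
#' @param threshold non-negative total-count cutoff.
#' @return filtered `ExpressionMatrix` with attribute `dropped_genes`.
#' @export
filter_low_counts <- function(x, threshold = 10) {
  stopifnot(inherits(x, "ExpressionMatrix"), threshold >= 0)
  keep <- rowSums(x$counts) >= threshold
  dropped <- x$gene_ids[!keep]
  if (!any(keep)) warning("all genes fall below the count threshold")
  out <- expression_matrix(x$counts[keep, , drop = FALSE],
                           gene_ids = x$gene_ids[keep],
                           gene_symbols = x$gene_symbols[keep],
                           lengths = x$lengths[keep])
  attr(out, "dropped_genes") <- dropped
  out
}

#' Differential-expression filter on an L2FC table
#'
#' Returns the genes with `|l2fc| >= min_abs_l2fc` and
#' `adj_p <= max_adj_p`.
#'
#' @param l2fc `L2FCTable`.
#' @param min_abs_l2fc default 2.
#' @param max_adj_p default 0.05.
#' @param require_p if `TRUE` (default) a missing `adj_p` column is an error;
#'   set `FALSE` to filter on fold change alone.
#' @return character vector of gene symbols.
#' @export
de_filter <- function(l2fc, min_abs_l2fc = 2, max_adj_p = 0.05,
                      require_p = TRUE) {
  has_p <- "adj_p" %in% names(l2fc)
  if (!has_p && require_p) {
    stop("L2FC table has no adj_p column; set require_p = FALSE to filter on ",
         "fold change alone")
  }
  sel <- abs(l2fc$l2fc) >= min_abs_l2fc
  if (has_p) sel <- sel & !is.na(l2fc$adj_p) & l2fc$adj_p <= max_adj_p
  l2fc$gene[sel]
}
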