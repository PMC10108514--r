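#' Screen configuration
#'
#' @param cv_threshold CV cutoff defining a "qualifying" CV (default 0.15).
#' @param top_k shortlist size (default 4).
#' @param sd_type `"sample"` (n-1 denominator, default; per-line sample counts
#'   are small) or `"population"`.
#' @param l2fc_floor divisor floor used when the minimal |l2fc| is exactly 0.
#' @param exclusion_policy `"warn"` or `"drop"` for hypoxia-inducible genes.
#' @return list of class `ScreenConfig`.
#' @export
screen_config <- function(cv_threshold = 0.15, top_k = 4,
                          sd_type = c("sample", "population"),
                          l2fc_floor = 1e-3,
                          exclusion_policy = c("warn", "drop")) {
  stopifnot(cv_threshold > 0, top_k >= 1, l2fc_floor > 0)
  structure(list(cv_threshold = cv_threshold, top_k = top_k,
                 sd_type = match.arg(sd_type), l2fc_floor = l2fc_floor,
                 exclusion_policy = match.arg(exclusion_policy)),
            class = "ScreenConfig")
}

sd_fun <- function(type) {
  if (type == "population") {
    function(v) sqrt(mean((v - mean(v))^2))
  } else {
    stats::sd
  }
}

#' Per-cell-line coefficients of variation for candidate genes
#'
#' For each candidate and each cell line, the test- and control-condition
#' samples of that line are pooled and CV = SD / mean of the normalized
#' values is computed; a pooled record across all lines (`cell_line = "ALL"`)
#' is added. Genes with mean 0 in a block get `cv = NA` and are flagged;
#' they never qualify.
#'
#' @param norm `NormalizedMatrix`.
#' @param ann `SampleAnnotation` for the matrix's samples.
#' @param candidates character vector of candidate symbols (case-insensitive
#'   match against the matrix symbols; unmatched candidates are dropped with
#'   a warning).
#' @param config [screen_config()].
#' @return data.frame with columns gene, cell_line, norm_method, cv,
#'   n_samples, flagged.
#' @export
compute_cv <- function(norm, ann, candidates, config = screen_config()) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  ann <- ann[match(colnames(norm$values), ann$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotation does not cover all samples")
  idx <- match_symbols(candidates, norm$gene_symbols)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no candidate matched the matrix")
  sdf <- sd_fun(config$sd_type)
  lines <- c(sort(unique(ann$cell_line)), "ALL")
  rows <- lapply(lines, function(cl) {
    cols <- if (cl == "ALL") seq_len(nrow(ann)) else which(ann$cell_line == cl)
    if (length(cols) < 2) {
      stop("cell line ", cl, " has fewer than 2 samples")
    }
    vals <- norm$values[idx, cols, drop = FALSE]
    m <- rowMeans(vals)
    s <- apply(vals, 1, sdf)
    cv <- ifelse(m > 0, s / m, NA_real_)
    data.frame(gene = names(idx), cell_line = cl, norm_method = norm$method,
               cv = cv, n_samples = length(cols), flagged = m <= 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean qualifying CV for one gene
#'
#' Average of the CVs at or below the threshold; `NA` (ineligible) when none
#' qualify. Ineligibility is a value, not an error.
#'
#' @param cvs numeric vector: the gene's per-line x per-method CV grid
#'   (pooled-`ALL` records excluded).
#' @param threshold qualifying cutoff.
#' @return list(cv_bar, n_qualifying).
#' @export
mean_qualifying_cv <- function(cvs, threshold = 0.15) {
  q <- cvs[!is.na(cvs) & cvs <= threshold]
  list(cv_bar = if (length(q)) mean(q) else NA_real_,
       n_qualifying = length(q))
}

#' Summarize CV records into per-gene qualifying means
#'
#' @param cv_records output of [compute_cv()] for one or more normalization
#'   methods, row-bound.
#' @param threshold qualifying CV cutoff.
#' @return data.frame gene, n_qualifying, cv_bar (per-line records only; the
#'   pooled `ALL` rows are reported but do not enter the qualifying grid).
#' @export
summarize_cv <- function(cv_records, threshold = 0.15) {
  per_line <- cv_records[cv_records$cell_line != "ALL", ]
  genes <- unique(per_line$gene)
  res <- lapply(genes, function(g) {
    mq <- mean_qualifying_cv(per_line$cv[per_line$gene == g], threshold)
    data.frame(gene = g, n_qualifying = mq$n_qualifying, cv_bar = mq$cv_bar,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank candidates by summed normalized CV and fold-change scores
#'
#' Eligible genes (at least one qualifying CV, finite l2fc) are scored by
#' `norm_cv = cv_bar / min(cv_bar)` plus `norm_l2fc = |l2fc| / min(|l2fc|)`
#' (the minimum being the value closest to zero), and ranked ascending by the
#' sum. Ties are broken by smaller `cv_bar`, then symbol order, and noted in
#' the `tie` column. If the minimal |l2fc| is exactly zero, that gene gets
#' `norm_l2fc = 1` and the others divide by `config$l2fc_floor` with a
#' warning.
#'
#' @param cv_summary output of [summarize_cv()].
#' @param l2fc `L2FCTable` covering the eligible genes.
#' @param config [screen_config()].
#' @return data.frame of class `RankingTable`: gene, n_qualifying, cv_bar,
#'   l2fc, norm_cv, norm_l2fc, score, rank, tie.
#' @export
rank_candidates <- function(cv_summary, l2fc, config = screen_config()) {
  tab <- merge(cv_summary, l2fc[, c("gene", "l2fc")], by = "gene", all.x = TRUE)
  eligible <- tab[!is.na(tab$cv_bar), , drop = FALSE]
  if (any(is.na(eligible$l2fc))) {
    stop("no l2fc for eligible gene(s): ",
         paste(eligible$gene[is.na(eligible$l2fc)], collapse = ", "))
  }
  if (nrow(eligible) < 2) stop("fewer than 2 eligible genes to rank")
  abs_l2fc <- abs(eligible$l2fc)
  min_cv <- min(eligible$cv_bar)
  min_l2 <- min(abs_l2fc)
  norm_cv <- eligible$cv_bar / min_cv
  if (min_l2 == 0) {
    warning("minimal |l2fc| is exactly 0; dividing the others by the floor ",
            config$l2fc_floor)
    norm_l2fc <- ifelse(abs_l2fc == 0, 1, abs_l2fc / config$l2fc_floor)
  } else {
    norm_l2fc <- abs_l2fc / min_l2
  }
  score <- norm_cv + norm_l2fc
  ord <- order(score, eligible$cv_bar, eligible$gene)
  out <- eligible[ord, , drop = FALSE]
  out$norm_cv <- norm_cv[ord]
  out$norm_l2fc <- norm_l2fc[ord]
  out$score <- score[ord]
  out$rank <- seq_len(nrow(out))
  out$tie <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  rownames(out) <- NULL
  class(out) <- c("RankingTable", "data.frame")
  out
}

#' Shortlist the top-ranked candidates
#'
#' @param table `RankingTable`.
#' @param k shortlist size, `1 <= k <=` number of ranked genes.
#' @return character vector of the first `k` gene symbols by rank.
#' @export
shortlist <- function(table, k) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(table)) {
    stop("k = ", k, " exceeds the ", nrow(table), " ranked genes")
  }
  table$gene[order(table$rank)][seq_len(k)]
}

#' Annotate or drop treatment-regulated genes from a ranking
#'
#' @param table `RankingTable`.
#' @param exclusion character vector of symbols known to be regulated by the
#'   treatment (case-insensitive).
#' @param policy `"warn"` (retain, flag) or `"drop"` (remove and re-rank).
#' @return the table with an `excluded_candidate` flag column (warn) or with
#'   the flagged genes removed and ranks recomputed (drop).
#' @export
apply_exclusion <- function(table, exclusion, policy = c("warn", "drop")) {
  policy <- match.arg(policy)
  hit <- toupper(table$gene) %in% toupper(exclusion)
  if (policy == "warn") {
    if (any(hit)) {
      warning("treatment-regulated candidate(s) retained: ",
              paste(table$gene[hit], collapse = ", "))
    }
    table$excluded_candidate <- hit
    table
  } else {
    out <- table[!hit, , drop = FALSE]
    out <- out[order(out$rank), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  }
}

#' Full RNA-seq housekeeping-gene screen
#'
#' Computes CVs under both TPM and median-of-ratios normalization for the
#' candidate genes, averages the qualifying CVs, attaches log2 fold changes
#' (external table if given, else the naive estimate), applies the exclusion
#' policy and ranks.
#'
#' @param x [expression_matrix()] (lengths needed for TPM).
#' @param ann `SampleAnnotation`.
#' @param candidates character vector of candidate symbols.
#' @param l2fc optional `L2FCTable`; when `NULL` the naive estimate from the
#'   size-factor-normalized values is used.
#' @param exclusion optional exclusion symbols.
#' @param config [screen_config()].
#' @param tpm_mode passed to [tpm_normalize()].
#' @param low_count_threshold passed to [filter_low_counts()].
#' @return list with `ranking` (RankingTable), `shortlist`, `cv_records`,
#'   `cv_summary`, `l2fc_source`.
#' @export
screen_candidates <- function(x, ann, candidates, l2fc = NULL,
                              exclusion = NULL, config = screen_config(),
                              tpm_mode = "standard",
                              low_count_threshold = 10) {
  ann <- match_annotation(x, ann)
  x <- filter_low_counts(x, low_count_threshold)
  norms <- list(tpm_normalize(x, mode = tpm_mode), size_factor_normalize(x))
  cv_records <- do.call(rbind, lapply(norms, compute_cv, ann = ann,
                                      candidates = candidates,
                                      config = config))
  cv_summary <- summarize_cv(cv_records, config$cv_threshold)
  if (is.null(l2fc)) {
    l2fc <- naive_l2fc(norms[[2]], ann)
  }
  ranking <- rank_candidates(cv_summary, l2fc, config)
  if (!is.null(exclusion) && length(exclusion)) {
    ranking <- apply_exclusion(ranking, exclusion, config$exclusion_policy)
  }
  k <- min(config$top_k, nrow(ranking))
  list(ranking = ranking, shortlist = shortlist(ranking, k),
       cv_records = cv_records, cv_summary = cv_summary,
       l2fc_source = attr(l2fc, "source"))
}
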