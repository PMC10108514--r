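#' Preprocess a long-format Ct table into a Ct matrix
#'
#' Applies the detection limit (entries flagged below-detection or with
#' `ct >= lod` are removed), averages technical replicates per
#' (gene, cell line, condition, run), and assembles a genes x samples matrix
#' where a sample is one (cell line, condition, run) combination. Entries
#' with no retained replicate are `NA`. QC notes are collected for replicate
#' means outside the usual raw-Ct working range and, per cell line, for gene
#' pairs further apart than `max_target_ref_gap` cycles (large target vs
#' reference gaps inflate amplification error).
#'
#' @param ct `CtTable` from [read_ct_table()] (or a data.frame with the same
#'   columns).
#' @param lod limit of detection in cycles; default 35.
#' @param qc_range usual raw-Ct working range, default `c(14, 32)`.
#' @param max_target_ref_gap maximal advisable Ct gap between genes, default 10.
#' @return list of class `CtMatrix`: `ct` (matrix), `samples` (metadata),
#'   `dropped` (genes excluded per line, with reason), `qc` (notes),
#'   `n_removed` (observations removed at the detection limit).
#' @export
preprocess_ct <- function(ct, lod = 35, qc_range = c(14, 32),
                          max_target_ref_gap = 10) {
  need <- c("gene", "cell_line", "condition", "run", "tech_rep", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table missing columns: ", paste(miss, collapse = ", "))
  if (!"below_detection" %in% names(ct)) ct$below_detection <- FALSE
  drop_obs <- ct$below_detection | (!is.na(ct$ct) & ct$ct >= lod)
  kept <- ct[!drop_obs, , drop = FALSE]
  qc <- data.frame(type = character(), message = character(),
                   stringsAsFactors = FALSE)

  key <- interaction(kept$gene, kept$cell_line, kept$condition, kept$run,
                     drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(kept, key), function(d) {
    data.frame(gene = d$gene[1], cell_line = d$cell_line[1],
               condition = d$condition[1], run = d$run[1],
               ct = mean(d$ct), n_reps = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  out_of_range <- agg[agg$ct < qc_range[1] | agg$ct > qc_range[2], , drop = FALSE]
  if (nrow(out_of_range)) {
    qc <- rbind(qc, data.frame(
      type = "ct_range",
      message = sprintf("%s %s/%s run %s mean Ct %.1f outside [%g, %g]",
                        out_of_range$gene, out_of_range$cell_line,
                        out_of_range$condition, out_of_range$run,
                        out_of_range$ct, qc_range[1], qc_range[2]),
      stringsAsFactors = FALSE))
  }

  genes <- unique(ct$gene)
  samples <- unique(ct[, c("cell_line", "condition", "run")])
  samples <- samples[order(samples$cell_line, samples$condition, samples$run), ]
  samples$sample_id <- paste(samples$cell_line, samples$condition,
                             samples$run, sep = ".")
  rownames(samples) <- NULL
  mat <- matrix(NA_real_, nrow = length(genes), ncol = nrow(samples),
                dimnames = list(genes, samples$sample_id))
  sid <- paste(agg$cell_line, agg$condition, agg$run, sep = ".")
  mat[cbind(match(agg$gene, genes), match(sid, samples$sample_id))] <- agg$ct

  # per-(gene, line) tally of observations removed at the detection limit
  rem <- ct[drop_obs, , drop = FALSE]
  if (nrow(rem)) {
    bdkey <- interaction(rem$gene, rem$cell_line, drop = TRUE, sep = "\r")
    bd_by_line <- do.call(rbind, lapply(split(rem, bdkey), function(d) {
      data.frame(gene = d$gene[1], cell_line = d$cell_line[1],
                 n_below = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(bd_by_line) <- NULL
  } else {
    bd_by_line <- data.frame(gene = character(), cell_line = character(),
                             n_below = integer(), stringsAsFactors = FALSE)
  }

  dropped <- data.frame(gene = character(), cell_line = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (cl in unique(samples$cell_line)) {
    cols <- which(samples$cell_line == cl)
    gone <- genes[rowSums(!is.na(mat[, cols, drop = FALSE])) == 0]
    if (length(gone)) {
      dropped <- rbind(dropped, data.frame(
        gene = gone, cell_line = cl,
        reason = "no observation above detection limit",
        stringsAsFactors = FALSE))
    }
    # pairwise gene gaps within the line, on per-gene mean Ct
    gm <- rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
    gm <- gm[is.finite(gm)]
    if (length(gm) >= 2 && diff(range(gm)) > max_target_ref_gap) {
      wide <- range(gm)
      qc <- rbind(qc, data.frame(
        type = "target_ref_gap",
        message = sprintf("line %s: gene mean Cts span %.1f cycles (> %g): %s=%.1f vs %s=%.1f",
                          cl, diff(wide), max_target_ref_gap,
                          names(gm)[which.min(gm)], wide[1],
                          names(gm)[which.max(gm)], wide[2]),
        stringsAsFactors = FALSE))
    }
  }

  structure(list(ct = mat, samples = samples, dropped = dropped,
                 below_detection = bd_by_line, qc = qc,
                 n_removed = sum(drop_obs)),
            class = "CtMatrix")
}

#' @export
print.CtMatrix <- function(x, ...) {
  cat(sprintf("CtMatrix: %d genes x %d samples (%d lines; %d obs removed at LOD)\n",
              nrow(x$ct), ncol(x$ct), length(unique(x$samples$cell_line)),
              x$n_removed))
  invisible(x)
}

# subset a CtMatrix to one cell line
subset_ct_line <- function(m, line) {
  cols <- which(m$samples$cell_line == line)
  list(ct = m$ct[, cols, drop = FALSE],
       samples = m$samples[cols, , drop = FALSE])
}

# pairwise-complete SD of Ct differences between two gene rows;
# NA when fewer than min_common common samples
pair_sd <- function(a, b, min_common = 2) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_common) return(NA_real_)
  stats::sd(a[ok] - b[ok])
}

#' GeNorm expression stability (M values)
#'
#' Ct values are converted to relative quantities `q = 2^(minCt_g - Ct_gs)`;
#' for each gene pair the SD over samples of the pairwise log2 ratio is
#' computed (pairwise-complete), and `M_g` is the mean over the other genes.
#' Lower M = more stable. The classic stepwise procedure (iteratively remove
#' the highest-M gene) and the pairwise variation `V_{n/n+1}` of
#' normalization factors are also returned. Gene ranks are taken from the
#' full-panel M values; the stepwise procedure cannot split the last pair.
#'
#' @param ct numeric matrix, genes x samples (mean Ct; `NA` allowed).
#' @param min_common minimal number of common samples for a pair, default 2;
#'   pairs below it are skipped with a warning.
#' @return list with `M` (full-panel), `rank`, `exclusion_order` (first
#'   removed first), `V` (named `V2/3`, ...), `stepwise_M`.
#' @export
genorm <- function(ct, min_common = 2) {
  k <- nrow(ct)
  if (k < 2) stop("genorm needs at least 2 genes")
  if (ncol(ct) < 2) stop("genorm needs at least 2 samples")
  q <- 2^(apply(ct, 1, min, na.rm = TRUE) - ct)   # relative quantities
  lq <- log2(q)
  M_of <- function(rows) {
    sapply(rows, function(g) {
      sds <- sapply(setdiff(rows, g), function(h) {
        pair_sd(lq[g, ], lq[h, ], min_common)
      })
      if (all(is.na(sds))) NA_real_ else mean(sds, na.rm = TRUE)
    })
  }
  genes <- rownames(ct)
  if (is.null(genes)) genes <- as.character(seq_len(k))
  rownames(lq) <- genes
  M_full <- stats::setNames(M_of(genes), genes)
  if (anyNA(M_full)) {
    warning("gene pair(s) with insufficient common samples were skipped")
  }

  # stepwise exclusion
  remaining <- genes
  exclusion <- character()
  stepwise <- list()
  while (length(remaining) > 2) {
    M <- M_of(remaining)
    stepwise[[length(stepwise) + 1L]] <- stats::setNames(M, remaining)
    worst <- remaining[order(-M, remaining)][1]
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  stability_order <- c(rev(remaining), rev(exclusion))  # most stable first

  # pairwise variation V_{n/n+1}: normalization factor = geometric mean of
  # the top-n genes' quantities
  V <- numeric(0)
  if (k >= 3) {
    nf <- function(n) {
      rows <- stability_order[seq_len(n)]
      apply(lq[rows, , drop = FALSE], 2, function(col) {
        if (anyNA(col)) NA_real_ else mean(col)  # log2 of geometric mean
      })
    }
    for (n in 2:(k - 1)) {
      d <- nf(n) - nf(n + 1)
      V[sprintf("V%d/%d", n, n + 1)] <- stats::sd(d, na.rm = TRUE)
    }
  }
  rank <- rank_scores(M_full)
  list(M = M_full, rank = rank, exclusion_order = exclusion,
       stability_order = stability_order, V = V, stepwise_M = stepwise)
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (g, h), `dCt_s = Ct_gs - Ct_hs`; the stability
#' of g is the mean over the other genes of the SD over samples of `dCt`
#' (pairwise-complete). Lower = more stable.
#'
#' @inheritParams genorm
#' @return named numeric vector of stabilities.
#' @export
delta_ct_method <- function(ct, min_common = 2) {
  k <- nrow(ct)
  if (k < 2) stop("delta_ct_method needs at least 2 genes")
  genes <- rownames(ct)
  if (is.null(genes)) genes <- as.character(seq_len(k))
  out <- sapply(seq_len(k), function(g) {
    sds <- sapply(setdiff(seq_len(k), g), function(h) {
      pair_sd(ct[g, ], ct[h, ], min_common)
    })
    if (all(is.na(sds))) NA_real_ else mean(sds, na.rm = TRUE)
  })
  stats::setNames(out, genes)
}

#' BestKeeper descriptive stability
#'
#' Per-gene descriptive statistics on raw mean Ct (arithmetic mean, SD,
#' CV% = 100 SD/mean) and the Pearson correlation of each gene with the
#' BestKeeper index, the per-sample geometric mean of the candidate Ct
#' values (computed over the genes available in that sample). Stability
#' ordering is by SD ascending, ties by larger correlation.
#'
#' @inheritParams genorm
#' @return data.frame gene, n, mean, sd, cv_pct, r, plus attribute `index`.
#' @export
bestkeeper <- function(ct) {
  if (nrow(ct) < 2) stop("bestkeeper needs at least 2 genes")
  if (ncol(ct) < 2) stop("bestkeeper needs at least 2 samples")
  genes <- rownames(ct)
  index <- apply(ct, 2, function(col) {
    v <- col[!is.na(col)]
    if (!length(v)) NA_real_ else exp(mean(log(v)))
  })
  if (isTRUE(stats::sd(index, na.rm = TRUE) == 0)) {
    warning("BestKeeper index has zero variance; correlations undefined")
  }
  res <- data.frame(
    gene = genes,
    n = rowSums(!is.na(ct)),
    mean = rowMeans(ct, na.rm = TRUE),
    sd = apply(ct, 1, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE)
  res$cv_pct <- 100 * res$sd / res$mean
  res$r <- apply(ct, 1, function(row) {
    ok <- !is.na(row) & !is.na(index)
    if (sum(ok) < 3 || stats::sd(row[ok]) == 0 || stats::sd(index[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(row[ok], index[ok])
  })
  attr(res, "index") <- index
  rownames(res) <- NULL
  res
}

#' NormFinder model-based stability
#'
#' Fits the additive two-way model of log-scale expression (negated Ct):
#' expression = gene effect + sample effect + error, per condition group,
#' and combines the estimated per-gene intragroup variance with the shrunken
#' intergroup (condition) difference into a stability value
#' `|shrunken difference| + sqrt(mean_g intragroup variance / n_g)`; lower =
#' more stable. When `groups` is `NULL` or any group has fewer than 2
#' samples is an error; use `ungrouped = TRUE` for the single-group variant
#' (stability = sqrt of the estimated gene variance).
#'
#' @param ct genes x samples matrix of mean Ct.
#' @param groups character/factor of length ncol(ct) with exactly two levels,
#'   or `NULL` with `ungrouped = TRUE`.
#' @param ungrouped use the single-group variant.
#' @param na_action `"error"` (default) or `"impute"`: impute missing entries
#'   with the gene's mean within its group (a gene missing an entire group
#'   cannot be imputed and is an error; exclude such genes first).
#' @return named numeric vector of stability values, with attributes
#'   `intragroup_var` (genes x groups) and `group_diff` (shrunken).
#' @export
normfinder <- function(ct, groups = NULL, ungrouped = is.null(groups),
                       na_action = c("error", "impute")) {
  na_action <- match.arg(na_action)
  k <- nrow(ct)
  if (k < 3) stop("normfinder needs at least 3 genes")
  genes <- rownames(ct)
  if (is.null(genes)) genes <- as.character(seq_len(k))
  x <- -ct   # log2 expression scale
  if (ungrouped) {
    groups <- rep("all", ncol(ct))
  } else {
    groups <- as.character(groups)
    if (length(unique(groups)) != 2) stop("normfinder expects exactly 2 groups")
  }
  glev <- unique(groups)
  ns <- table(groups)
  if (any(ns < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(ns)[ns < 2], collapse = ", "))
  }
  sigma2 <- matrix(NA_real_, k, length(glev), dimnames = list(genes, glev))
  d <- matrix(NA_real_, k, length(glev), dimnames = list(genes, glev))
  for (g in glev) {
    X <- x[, groups == g, drop = FALSE]
    if (anyNA(X)) {
      if (na_action == "error") {
        stop("missing values in group ", g,
             "; use na_action = 'impute' or exclude the gene")
      }
      rm_ <- rowMeans(X, na.rm = TRUE)
      if (any(!is.finite(rm_))) {
        stop("gene(s) with no observation in group ", g, ": ",
             paste(genes[!is.finite(rm_)], collapse = ", "))
      }
      X[is.na(X)] <- rm_[row(X)[is.na(X)]]
    }
    n <- ncol(X)
    z <- sweep(X, 2, colMeans(X))       # remove sample effects
    s2 <- apply(z, 1, stats::var)       # (n-1) denominator, gene-centered in j
    S <- sum(s2)
    sigma2[, g] <- pmax((s2 - S / (k * (k - 1))) * k / (k - 2), 0)
    d[, g] <- rowMeans(z)
  }
  if (length(glev) == 1) {
    out <- sqrt(sigma2[, 1])
    attr(out, "intragroup_var") <- sigma2
    attr(out, "group_diff") <- NULL
    return(out)
  }
  cmat <- d - rowMeans(d)               # gene-centered group differences
  nvec <- as.numeric(ns[glev])
  varg <- sweep(sigma2, 2, nvec, "/")   # sigma2_ig / n_g
  gamma2 <- max(0, sum(cmat^2) / ((k - 1) * (length(glev) - 1)) - mean(varg))
  shrink <- if (gamma2 > 0) gamma2 / (gamma2 + varg) else 0 * varg
  ctilde <- cmat * shrink
  out <- rowMeans(abs(ctilde)) + sqrt(rowMeans(varg))
  names(out) <- genes
  attr(out, "intragroup_var") <- sigma2
  attr(out, "group_diff") <- ctilde
  out
}

#' RefFinder-style rank aggregation
#'
#' Geometric mean of the per-method ranks from the four stability methods;
#' the final rank is the ascending order of geometric means, ties broken by
#' the comparative delta-Ct rank, then gene name.
#'
#' @param ranks genes x methods matrix/data.frame of complete 1..n rankings;
#'   must contain a column named `delta_ct` for tie-breaking.
#' @return list with `geomean` and `rank` (named vectors).
#' @export
reffinder_aggregate <- function(ranks) {
  ranks <- as.matrix(ranks)
  if (anyNA(ranks)) stop("missing method ranking in RefFinder aggregation")
  if (is.null(colnames(ranks)) || !"delta_ct" %in% colnames(ranks)) {
    stop("ranks must have named columns including 'delta_ct'")
  }
  n <- nrow(ranks)
  for (j in seq_len(ncol(ranks))) {
    if (!setequal(ranks[, j], seq_len(n))) {
      stop("column '", colnames(ranks)[j], "' is not a complete 1..n ranking")
    }
  }
  gm <- exp(rowMeans(log(ranks)))
  rank <- rank_scores(gm, tb = ranks[, "delta_ct"])
  list(geomean = gm, rank = rank)
}

#' Livak 2^-ddCt relative quantification
#'
#' Within each (cell line, run), the reference Ct is the arithmetic mean of
#' the reference genes' mean Ct (equivalent to the geometric mean of their
#' linear quantities); `dCt = Ct_target - Ct_ref` per condition,
#' `ddCt = dCt_test - dCt_control`, fold `= 2^-ddCt`. Runs missing the
#' target or a reference in either condition are skipped with a note.
#' Per-line ddCt is averaged over usable runs before conversion; folds are
#' reported in the signed convention (values below 1 as -1/fold).
#'
#' @param m `CtMatrix` from [preprocess_ct()].
#' @param target target gene symbol.
#' @param references character vector of reference gene symbols.
#' @param test,ctrl condition labels (default `"Hx"` / `"Nx"`).
#' @return list of class `FoldResult`: `per_run` (line, run, ddct, fold),
#'   `per_line` (line, ddct, fold), `mean_fold`, `sd_fold`, `skipped`.
#' @export
livak_fold <- function(m, target, references, test = "Hx", ctrl = "Nx") {
  stopifnot(inherits(m, "CtMatrix"))
  genes <- rownames(m$ct)
  if (!target %in% genes) stop("target gene not in Ct matrix: ", target)
  missing_refs <- setdiff(references, genes)
  if (length(missing_refs)) {
    stop("reference gene(s) not in Ct matrix: ",
         paste(missing_refs, collapse = ", "))
  }
  sm <- m$samples
  per_run <- data.frame()
  skipped <- data.frame()
  for (cl in unique(sm$cell_line)) {
    for (rn in unique(sm$run[sm$cell_line == cl])) {
      col_t <- which(sm$cell_line == cl & sm$run == rn & sm$condition == test)
      col_c <- which(sm$cell_line == cl & sm$run == rn & sm$condition == ctrl)
      if (length(col_t) != 1 || length(col_c) != 1) next
      vals <- m$ct[c(target, references), c(col_t, col_c), drop = FALSE]
      if (anyNA(vals)) {
        skipped <- rbind(skipped, data.frame(
          cell_line = cl, run = rn,
          reason = "target or reference below detection",
          stringsAsFactors = FALSE))
        next
      }
      dct_t <- m$ct[target, col_t] - mean(m$ct[references, col_t])
      dct_c <- m$ct[target, col_c] - mean(m$ct[references, col_c])
      ddct <- dct_t - dct_c
      per_run <- rbind(per_run, data.frame(
        cell_line = cl, run = rn, ddct = ddct,
        fold = signed_fold(2^(-ddct)), stringsAsFactors = FALSE))
    }
  }
  if (nrow(skipped)) {
    warning(nrow(skipped), " line/run combination(s) skipped: reference or ",
            "target below detection")
  }
  if (!nrow(per_run)) stop("no usable line/run for the Livak computation")
  per_line <- do.call(rbind, lapply(split(per_run, per_run$cell_line), function(d) {
    dd <- mean(d$ddct)
    data.frame(cell_line = d$cell_line[1], n_runs = nrow(d), ddct = dd,
               fold = signed_fold(2^(-dd)), stringsAsFactors = FALSE)
  }))
  rownames(per_line) <- NULL
  structure(list(target = target, references = references,
                 per_run = per_run, per_line = per_line,
                 mean_fold = mean(per_line$fold),
                 sd_fold = stats::sd(per_line$fold),
                 skipped = skipped),
            class = "FoldResult")
}

#' Signed fold-change convention
#'
#' Maps a positive fold ratio to the signed convention: ratios below 1 are
#' reported as the negative reciprocal, so `|fold| >= 1` always.
#'
#' @param ratio positive fold ratio(s), e.g. `2^-ddCt`.
#' @return signed fold change(s).
#' @export
signed_fold <- function(ratio) {
  stopifnot(all(ratio > 0))
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' @export
print.FoldResult <- function(x, ...) {
  cat(sprintf("Livak 2^-ddCt: %s vs {%s}\n", x$target,
              paste(x$references, collapse = ", ")))
  print(x$per_line)
  cat(sprintf("mean fold %.2f +/- %.2f (n = %d lines)\n",
              x$mean_fold, x$sd_fold, nrow(x$per_line)))
  invisible(x)
}

# Livak-based stability: per line, score a gene by the mean |ddCt| of its
# condition response when every other candidate serves as reference in turn.
# D_g(run) = Ct_g,test - Ct_g,ctrl; ddCt(g | ref h) = D_g - D_h.
livak_stability <- function(ct, samples, test = "Hx", ctrl = "Nx") {
  genes <- rownames(ct)
  runs <- unique(samples$run)
  D <- matrix(NA_real_, length(genes), length(runs),
              dimnames = list(genes, runs))
  for (rn in runs) {
    ti <- which(samples$run == rn & samples$condition == test)
    ci <- which(samples$run == rn & samples$condition == ctrl)
    if (length(ti) == 1 && length(ci) == 1) D[, rn] <- ct[, ti] - ct[, ci]
  }
  sapply(genes, function(g) {
    diffs <- unlist(lapply(setdiff(genes, g), function(h) {
      d <- D[g, ] - D[h, ]
      d[!is.na(d)]
    }))
    if (!length(diffs)) NA_real_ else mean(abs(diffs))
  })
}

# deterministic ascending ranking: NA last, ties by tb then name
rank_scores <- function(x, tb = NULL, nm = names(x)) {
  n <- length(x)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (is.null(tb)) tb <- rep(0, n)
  o <- order(is.na(x), x, tb, nm)
  r <- integer(n)
  r[o] <- seq_len(n)
  stats::setNames(r, nm)
}

#' Combined per-line and overall stability ranking
#'
#' For each cell line, ranks the candidate genes with GeNorm, NormFinder,
#' BestKeeper (SD, ties by correlation), comparative delta-Ct, the RefFinder
#' geometric-mean aggregate of those four, and a Livak-based rank (mean
#' |ddCt| of each gene with every other candidate as reference). A gene with
#' no retained observation in a line, or missing an entire condition where a
#' method requires both, is assigned that line's worst rank, with a note.
#' The per-line final rank is the ascending rank of the mean of the six
#' method ranks (default) or of the RefFinder rank alone
#' (`variant = "reffinder"`); the overall rank re-ranks the arithmetic mean
#' of per-line final ranks.
#'
#' @param m `CtMatrix`.
#' @param test,ctrl condition labels.
#' @param variant `"six_method"` (default) or `"reffinder"` for the per-line
#'   final rank.
#' @param drop_policy when to exclude a gene from a line's analysis and rank
#'   it last there: `"any_below_detection"` (default; any observation of the
#'   gene removed at the detection limit in that line makes it unassessable
#'   as a reference) or `"all_missing"` (only when no observation remains).
#' @return list of class `StabilityReport`: `per_line` (named list of
#'   data.frames with method values and ranks), `overall` (gene, mean_rank,
#'   overall_rank for both variants), `notes`.
#' @export
combined_ranking <- function(m, test = "Hx", ctrl = "Nx",
                             variant = c("six_method", "reffinder"),
                             drop_policy = c("any_below_detection",
                                             "all_missing")) {
  stopifnot(inherits(m, "CtMatrix"))
  variant <- match.arg(variant)
  drop_policy <- match.arg(drop_policy)
  genes <- rownames(m$ct)
  lines <- unique(m$samples$cell_line)
  notes <- character()
  per_line <- list()

  for (cl in lines) {
    sub <- subset_ct_line(m, cl)
    retained <- genes[rowSums(!is.na(sub$ct)) > 0]
    if (drop_policy == "any_below_detection" && nrow(m$below_detection)) {
      flagged <- m$below_detection$gene[m$below_detection$cell_line == cl]
      retained <- setdiff(retained, flagged)
    }
    dropped_line <- sort(setdiff(genes, retained))
    if (length(dropped_line)) {
      notes <- c(notes, sprintf(
        "line %s: %s ranked last (%s)", cl,
        paste(dropped_line, collapse = ", "),
        if (drop_policy == "any_below_detection")
          "below detection limit in this line" else "no retained observation"))
    }
    if (length(retained) < 2) {
      notes <- c(notes, sprintf("line %s excluded: < 2 candidates retained", cl))
      next
    }
    ctl <- sub$ct[retained, , drop = FALSE]
    nline <- length(retained)

    gn <- genorm(ctl)
    dct <- delta_ct_method(ctl)
    bk <- bestkeeper(ctl)
    bk_rank <- rank_scores(bk$sd, tb = -abs(bk$r), nm = bk$gene)

    # NormFinder: genes observed in both conditions; grouped when each
    # condition has >= 2 samples in the line
    cond <- sub$samples$condition
    both <- retained[vapply(retained, function(g) {
      any(!is.na(ctl[g, cond == test])) && any(!is.na(ctl[g, cond == ctrl]))
    }, logical(1))]
    nf_rank <- stats::setNames(rep(nline, nline), retained)
    nf_val <- stats::setNames(rep(NA_real_, nline), retained)
    if (length(both) >= 3) {
      grouped <- min(table(cond)) >= 2
      nf <- normfinder(ctl[both, , drop = FALSE],
                       groups = if (grouped) cond else NULL,
                       ungrouped = !grouped, na_action = "impute")
      nf_val[both] <- nf
      nf_rank[] <- rank_scores(nf_val, nm = retained)
      if (length(both) < nline) {
        notes <- c(notes, sprintf(
          "line %s: %s excluded from NormFinder/Livak (one condition entirely below detection)",
          cl, paste(setdiff(retained, both), collapse = ", ")))
      }
    } else {
      notes <- c(notes, sprintf("line %s: NormFinder skipped (< 3 genes with both conditions)", cl))
      nf_rank[] <- rank_scores(nf_val, nm = retained)
    }

    lv_val <- livak_stability(ctl, sub$samples, test, ctrl)
    lv_rank <- rank_scores(lv_val, nm = retained)

    four <- cbind(genorm = gn$rank[retained],
                  normfinder = nf_rank[retained],
                  bestkeeper = bk_rank[retained],
                  delta_ct = rank_scores(dct)[retained])
    rf <- reffinder_aggregate(four)

    six <- cbind(four, reffinder = rf$rank[retained], livak = lv_rank[retained])
    mean_six <- rowMeans(six)
    final <- if (variant == "six_method") {
      rank_scores(mean_six, tb = rf$rank[retained], nm = retained)
    } else {
      rf$rank[retained]
    }

    df <- data.frame(
      gene = retained,
      analyzed = TRUE,
      genorm_m = gn$M[retained],
      normfinder_stability = nf_val[retained],
      bestkeeper_sd = bk$sd[match(retained, bk$gene)],
      bestkeeper_r = bk$r[match(retained, bk$gene)],
      delta_ct_mean_sd = dct[retained],
      livak_score = lv_val[retained],
      rank_genorm = six[, "genorm"],
      rank_normfinder = six[, "normfinder"],
      rank_bestkeeper = six[, "bestkeeper"],
      rank_delta_ct = six[, "delta_ct"],
      reffinder_geomean = rf$geomean[retained],
      rank_reffinder = six[, "reffinder"],
      rank_livak = six[, "livak"],
      final_rank = final,
      stringsAsFactors = FALSE)
    if (length(dropped_line)) {
      tail_ranks <- nline + seq_along(dropped_line)
      df <- rbind(df, data.frame(
        gene = dropped_line, analyzed = FALSE,
        genorm_m = NA_real_, normfinder_stability = NA_real_,
        bestkeeper_sd = NA_real_, bestkeeper_r = NA_real_,
        delta_ct_mean_sd = NA_real_, livak_score = NA_real_,
        rank_genorm = tail_ranks, rank_normfinder = tail_ranks,
        rank_bestkeeper = tail_ranks, rank_delta_ct = tail_ranks,
        reffinder_geomean = NA_real_, rank_reffinder = tail_ranks,
        rank_livak = tail_ranks, final_rank = tail_ranks,
        stringsAsFactors = FALSE))
    }
    per_line[[cl]] <- df
    rownames(per_line[[cl]]) <- NULL
  }

  if (!length(per_line)) stop("no cell line with >= 2 retained candidates")

  # overall: average per-line final ranks; genes absent from a line get that
  # line's worst rank + 1
  overall <- data.frame(gene = genes, stringsAsFactors = FALSE)
  rank_rows <- sapply(per_line, function(d) {
    r <- d$final_rank[match(genes, d$gene)]
    r[is.na(r)] <- nrow(d) + 1
    r
  })
  rf_rows <- sapply(per_line, function(d) {
    r <- d$rank_reffinder[match(genes, d$gene)]
    r[is.na(r)] <- nrow(d) + 1
    r
  })
  rank_rows <- matrix(rank_rows, nrow = length(genes))
  rf_rows <- matrix(rf_rows, nrow = length(genes))
  overall$mean_rank <- rowMeans(rank_rows)
  overall$mean_rank_reffinder <- rowMeans(rf_rows)
  overall$overall_rank <- rank_scores(overall$mean_rank,
                                      tb = overall$mean_rank_reffinder,
                                      nm = overall$gene)
  overall$overall_rank_reffinder <- rank_scores(overall$mean_rank_reffinder,
                                                tb = overall$mean_rank,
                                                nm = overall$gene)
  overall <- overall[order(overall$overall_rank), ]
  rownames(overall) <- NULL

  structure(list(per_line = per_line, overall = overall, notes = notes,
                 variant = variant),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf("StabilityReport (%s variant), %d line(s)\n", x$variant,
              length(x$per_line)))
  print(x$overall[, c("gene", "mean_rank", "overall_rank")])
  if (length(x$notes)) cat("notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
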