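#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: 5 donor cell lines,
#' each with 2 replicates per condition (test vs control), a minority of
#' genes treatment-regulated and a designated set of tightly controlled
#' stable genes; qPCR tables follow the validation design of 4 lines x 2
#' biological runs x 3 technical replicates with a detection limit at Ct 35.
#'
#' @param n_genes total genes.
#' @param n_stable genes simulated stable (l2fc 0) at low dispersion.
#' @param n_regulated genes given nonzero log2 condition effects.
#' @param n_lines donor cell lines.
#' @param reps_per_condition RNA-seq replicates per line and condition.
#' @param mean_depth mean library size (reads/sample).
#' @param dispersion named NB dispersions (Var = mu + a mu^2) for the
#'   `stable`, `regulated` and `background` gene classes.
#' @param regulated_l2fc recycled log2 effect sizes for regulated genes.
#' @param donor_sd SD (log2 scale) of the per-donor multiplicative offset.
#' @param ct_intercept baseline Ct of a gene of median abundance.
#' @param ct_tech_sd technical-replicate Ct noise SD.
#' @param ct_bio_sd biological (line x condition x run) Ct noise SD.
#' @param ct_lines,ct_runs,ct_tech_reps qPCR design: lines, biological runs
#'   per condition, technical replicates.
#' @param lod detection limit; simulated Ct at or above it is emitted as a
#'   below-detection marker.
#' @param test,control condition labels.
#' @param seed integer seed; identical configs give identical output.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 100, n_stable = 10, n_regulated = 20,
                       n_lines = 5, reps_per_condition = 2,
                       mean_depth = 1e6,
                       dispersion = c(stable = 0.01, regulated = 0.05,
                                      background = 0.1),
                       regulated_l2fc = c(1, -1, 2, -2, 3, -3),
                       donor_sd = 0.25,
                       ct_intercept = 25, ct_tech_sd = 0.2, ct_bio_sd = 0.3,
                       ct_lines = 4, ct_runs = 2, ct_tech_reps = 3,
                       lod = 35, test = "Hx", control = "Nx", seed = 1L) {
  stopifnot(n_genes >= 1, n_stable >= 0, n_regulated >= 0,
            n_stable + n_regulated <= n_genes,
            n_lines >= 1, reps_per_condition >= 1,
            all(dispersion > 0), donor_sd >= 0,
            ct_tech_sd >= 0, ct_bio_sd >= 0, lod > 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate an RNA-seq count matrix with known ground truth
#'
#' Counts are negative binomial:
#' `count ~ NB(mean = depth * base * 2^donor * 2^(l2fc * is_test),
#' dispersion)` with `Var = mu + a mu^2`. Gene lengths are log-uniform on
#' 500-10000 bp. The annotation mirrors the design (lines x conditions x
#' replicates).
#'
#' @param config [sim_config()].
#' @return list with `matrix` ([expression_matrix()]), `annotation`
#'   (`SampleAnnotation`) and `truth` (data.frame gene, class, true_l2fc,
#'   dispersion, base; plus attribute `donor_effects`).
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("G%03d", seq_len(ng))
  class <- rep("background", ng)
  if (config$n_stable > 0) class[seq_len(config$n_stable)] <- "stable"
  if (config$n_regulated > 0) {
    class[config$n_stable + seq_len(config$n_regulated)] <- "regulated"
  }
  true_l2fc <- numeric(ng)
  true_l2fc[class == "regulated"] <-
    rep_len(config$regulated_l2fc, config$n_regulated)
  dispersion <- unname(config$dispersion[class])

  base <- exp(stats::rnorm(ng, 0, 1.5))
  base <- base / sum(base)                     # relative abundance
  lengths <- round(exp(stats::runif(ng, log(500), log(10000))))

  lines <- LETTERS[seq_len(config$n_lines)]
  ann <- expand.grid(replicate = seq_len(config$reps_per_condition),
                     condition = c(config$test, config$control),
                     cell_line = lines, stringsAsFactors = FALSE)
  ann <- ann[, c("cell_line", "condition", "replicate")]
  ann$sample_id <- sprintf("%s_%s_%d", ann$cell_line, ann$condition,
                           ann$replicate)
  donor <- stats::setNames(stats::rnorm(length(lines), 0, config$donor_sd),
                           lines)
  counts <- matrix(0L, ng, nrow(ann), dimnames = list(genes, ann$sample_id))
  for (s in seq_len(nrow(ann))) {
    eff <- true_l2fc * (ann$condition[s] == config$test)
    mu <- config$mean_depth * base * 2^(donor[ann$cell_line[s]] + eff)
    counts[, s] <- stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
  }
  truth <- data.frame(gene = genes,
                      class = ifelse(class == "regulated", "regulated", "stable"),
                      subclass = class, true_l2fc = true_l2fc,
                      dispersion = dispersion, base = base,
                      stringsAsFactors = FALSE)
  attr(truth, "donor_effects") <- donor
  list(matrix = expression_matrix(counts, gene_ids = genes, lengths = lengths),
       annotation = sample_annotation(ann, test = config$test,
                                      control = config$control),
       truth = truth)
}

#' Simulate a long-format qRT-PCR Ct table from ground truth
#'
#' `Ct = ct_intercept - log2(base/median(base)) - donor - l2fc * is_test +
#' N(0, ct_bio_sd)` per (gene, line, condition, run), plus
#' `N(0, ct_tech_sd)` per technical replicate (amplification efficiency
#' exactly 2). Values at or above the detection limit become below-detection
#' markers.
#'
#' @param config [sim_config()].
#' @param truth ground-truth data.frame from [simulate_counts()]; when `NULL`
#'   a fresh one is drawn from the config.
#' @return `CtTable` data.frame (gene, cell_line, condition, run, tech_rep,
#'   ct, below_detection).
#' @export
simulate_ct <- function(config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(truth)) truth <- simulate_counts(config)$truth
  set.seed(config$seed + 1L)
  donor_all <- attr(truth, "donor_effects")
  lines <- LETTERS[seq_len(config$ct_lines)]
  donor <- stats::setNames(
    ifelse(lines %in% names(donor_all), donor_all[lines],
           stats::rnorm(length(lines), 0, config$donor_sd)),
    lines)
  base_ct <- config$ct_intercept -
    log2(truth$base / stats::median(truth$base))
  rows <- list()
  for (cl in lines) {
    for (cond in c(config$test, config$control)) {
      for (rn in seq_len(config$ct_runs)) {
        bio <- stats::rnorm(nrow(truth), 0, config$ct_bio_sd)
        mu_ct <- base_ct - donor[cl] -
          truth$true_l2fc * (cond == config$test) + bio
        for (tr in seq_len(config$ct_tech_reps)) {
          ct <- mu_ct + stats::rnorm(nrow(truth), 0, config$ct_tech_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = truth$gene, cell_line = cl, condition = cond,
            run = as.character(rn), tech_rep = tr,
            ct = round(ct, 2), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$below_detection <- out$ct >= config$lod
  out$ct[out$below_detection] <- NA_real_
  class(out) <- c("CtTable", "data.frame")
  out
}

#' Write a simulated dataset to disk
#'
#' Writes a featureCounts-dialect counts TSV (so gene lengths round-trip
#' through [read_counts()]), annotation CSV, Ct CSV (below-detection entries
#' as `">lod"`) and truth JSON under `dir`.
#'
#' @param config [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_simulation <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(config)
  ctab <- simulate_ct(config, sim$truth)
  ng <- length(sim$matrix$gene_ids)
  counts_df <- data.frame(Geneid = sim$matrix$gene_ids,
                          Chr = "chrS", Start = seq_len(ng),
                          End = seq_len(ng) + sim$matrix$lengths - 1,
                          Strand = "+", Length = sim$matrix$lengths,
                          sim$matrix$counts, check.names = FALSE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    annotation = file.path(dir, "annotation.csv"),
    ct = file.path(dir, "ct.csv"),
    truth = file.path(dir, "truth.json"))
  writeLines("# simulated counts, featureCounts dialect", paths$counts)
  suppressWarnings(utils::write.table(counts_df, paths$counts, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  utils::write.csv(as.data.frame(sim$annotation), paths$annotation,
                   row.names = FALSE)
  ct_out <- ctab
  ct_out$ct <- ifelse(ct_out$below_detection, paste0(">", config$lod),
                      format(ct_out$ct, trim = TRUE))
  ct_out$below_detection <- NULL
  utils::write.csv(ct_out, paths$ct, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
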