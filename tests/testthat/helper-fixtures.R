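# Small fixtures built in code.

toy_matrix <- function() {
  counts <- matrix(c(10, 4, 20, 8, 30, 12), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expression_matrix(counts, lengths = c(1000, 2000, 500))
}

toy_annotation <- function(lines = c("A", "B"), reps = 2) {
  df <- expand.grid(replicate = seq_len(reps), condition = c("Hx", "Nx"),
                    cell_line = lines, stringsAsFactors = FALSE)
  df$sample_id <- sprintf("%s_%s_%d", df$cell_line, df$condition, df$replicate)
  sample_annotation(df[, c("sample_id", "cell_line", "condition", "replicate")])
}

# deterministic genes x samples Ct grid with no special structure
toy_ct_grid <- function(ngene = 3, nsamp = 4, seed = 42) {
  set.seed(seed)
  matrix(round(stats::runif(ngene * nsamp, 18, 30), 2),
         nrow = ngene,
         dimnames = list(paste0("g", seq_len(ngene)),
                         paste0("s", seq_len(nsamp))))
}

# long-format Ct table from a per-(gene, line, condition, run) mean grid
ct_table_from_means <- function(means) {
  # means: data.frame gene, cell_line, condition, run, ct
  means$tech_rep <- 1L
  means$below_detection <- FALSE
  class(means) <- c("CtTable", "data.frame")
  means[, c("gene", "cell_line", "condition", "run", "tech_rep", "ct",
            "below_detection")]
}

table3_matrix <- function() {
  preprocess_ct(read_ct_table(builtin_file("qpcr_ct")))
}

write_temp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
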