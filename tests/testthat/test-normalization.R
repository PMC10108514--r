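test_that("standard TPM matches direct two-step arithmetic", {
  # lone gene takes the whole library
  x1 <- expression_matrix(matrix(10, 1, 1, dimnames = list("g", "s")),
                          lengths = 1000)
  expect_equal(unname(tpm_normalize(x1)$values[1, 1]), 1e6)

  # equal length-normalized rates split the million evenly
  x2 <- expression_matrix(matrix(c(10, 20), 2, 1,
                                 dimnames = list(c("a", "b"), "s")),
                          lengths = c(1000, 2000))
  expect_equal(unname(tpm_normalize(x2)$values[, 1]), c(5e5, 5e5))

  # 3x2 fixture against an explicitly hand-rolled oracle
  counts <- matrix(c(7, 13, 2, 31, 11, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  lengths <- c(1500, 800, 3000)
  expected <- counts * NA
  for (s in 1:2) {
    rate <- numeric(3)
    for (g in 1:3) rate[g] <- counts[g, s] / (lengths[g] / 1000)
    for (g in 1:3) expected[g, s] <- rate[g] / sum(rate) * 1e6
  }
  got <- tpm_normalize(expression_matrix(counts, lengths = lengths))$values
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("literal TPM divides rates by library size in millions", {
  counts <- matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s"))
  x <- expression_matrix(counts, lengths = c(1000, 2000))
  got <- tpm_normalize(x, mode = "literal")$values[, 1]
  # rates {10, 10}; depth 30/1e6
  expect_equal(unname(got), c(10, 10) / (30 / 1e6))
})

test_that("TPM preconditions: lengths required, zero library size fatal", {
  x <- expression_matrix(matrix(1:4, 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(tpm_normalize(x), "length")
  y <- expression_matrix(matrix(c(0, 0, 1, 2), 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))),
                         lengths = c(100, 100))
  expect_error(tpm_normalize(y), "library size")
})

test_that("standard TPM columns sum to 1e6 and are scale invariant", {
  set.seed(11)
  counts <- matrix(rpois(60, 50), 6, 10)
  dimnames(counts) <- list(paste0("g", 1:6), paste0("s", 1:10))
  x <- expression_matrix(counts, lengths = sample(500:5000, 6))
  v <- tpm_normalize(x)$values
  expect_equal(unname(colSums(v)), rep(1e6, 10), tolerance = 1e-6)
  # scaling one sample's counts leaves its TPM unchanged
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 7
  v2 <- tpm_normalize(expression_matrix(counts2, lengths = x$lengths))$values
  expect_equal(v2[, 3], v[, 3], tolerance = 1e-12)
})

test_that("median-of-ratios size factors match a brute-force oracle", {
  # identical samples
  c1 <- matrix(c(5, 9, 3, 5, 9, 3), 3, 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  n1 <- size_factor_normalize(expression_matrix(c1))
  expect_equal(unname(n1$parameters$size_factors), c(1, 1))

  # doubled sample scales its factor by 2 (geometric-mean centering)
  c2 <- cbind(s1 = c(5, 9, 3), s2 = 2 * c(5, 9, 3))
  rownames(c2) <- paste0("g", 1:3)
  sf <- size_factor_normalize(expression_matrix(c2))$parameters$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2)

  # 5x4 fixture vs direct per-sample median computation
  set.seed(3)
  counts <- matrix(rpois(20, 40) + 1, 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  counts[2, 3] <- 0   # g2 excluded from the reference set
  expected_sf <- numeric(4)
  ref <- which(apply(counts > 0, 1, all))
  geo <- apply(counts[ref, ], 1, function(r) prod(r)^(1 / length(r)))
  # median of ratios, interpolated geometrically (log-scale median)
  for (s in 1:4) expected_sf[s] <- exp(median(log(counts[ref, s] / geo)))
  got <- size_factor_normalize(expression_matrix(counts))
  expect_equal(unname(got$parameters$size_factors), expected_sf,
               tolerance = 1e-12)
  expect_equal(got$values, sweep(counts, 2, expected_sf, "/"),
               tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 estimator", {
  set.seed(8)
  counts <- matrix(rnbinom(80, mu = 100, size = 10) + 1, 8, 10,
                   dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  ours <- size_factor_normalize(expression_matrix(counts))$parameters$size_factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("size-factor preconditions", {
  x <- expression_matrix(matrix(1:2, 2, 1, dimnames = list(c("a", "b"), "s")))
  expect_error(size_factor_normalize(x), "2 samples")
  y <- expression_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(size_factor_normalize(y), "positive counts")
})

test_that("naive l2fc: exact cases, swap negation and NB recovery", {
  ann <- toy_annotation(lines = "A", reps = 2)
  vals <- rbind(flat = c(4, 4, 4, 4), up = c(8, 8, 1, 1))
  colnames(vals) <- ann$sample_id
  norm <- hkgselect:::normalized_matrix(
    vals, list(gene_ids = rownames(vals), gene_symbols = rownames(vals)),
    "tpm", list())
  res <- naive_l2fc(norm, ann, pseudocount = 0)
  expect_equal(res$l2fc[res$gene == "flat"], 0)
  expect_equal(res$l2fc[res$gene == "up"], 3)

  # condition swap negates every l2fc at pc = 0
  ann_sw <- sample_annotation(as.data.frame(ann), test = "Nx", control = "Hx")
  res_sw <- naive_l2fc(norm, ann_sw, pseudocount = 0)
  expect_equal(res_sw$l2fc, -res$l2fc)

  # NB simulation with true l2fc 2, dispersion 0.05, n = 20/group
  set.seed(99)
  n <- 20
  test_counts <- rnbinom(n, mu = 400, size = 1 / 0.05)
  ctrl_counts <- rnbinom(n, mu = 100, size = 1 / 0.05)
  vals2 <- matrix(c(test_counts, ctrl_counts), nrow = 1,
                  dimnames = list("g", paste0("s", 1:(2 * n))))
  ann2 <- sample_annotation(data.frame(
    sample_id = paste0("s", 1:(2 * n)), cell_line = "A",
    condition = rep(c("Hx", "Nx"), each = n), replicate = 1))
  norm2 <- hkgselect:::normalized_matrix(
    vals2, list(gene_ids = "g", gene_symbols = "g"), "size_factor", list())
  est <- naive_l2fc(norm2, ann2, pseudocount = 0)$l2fc
  expect_lt(abs(est - 2), 0.2)
})

test_that("signed fold conversion is odd-symmetric with |fold| >= 1", {
  expect_equal(l2fc_to_fold(0), 1)
  xs <- c(0.1, 0.53, 1.23, 2, 5)
  expect_equal(l2fc_to_fold(-xs), -l2fc_to_fold(xs))
  expect_true(all(abs(l2fc_to_fold(c(-xs, 0, xs))) >= 1))
  expect_error(l2fc_to_fold(Inf), "finite")
})

test_that("low-count filter drops genes below the total-count threshold", {
  counts <- rbind(lo = c(4, 5), hi = c(50, 60))
  colnames(counts) <- c("s1", "s2")
  x <- expression_matrix(counts, lengths = c(100, 100))
  f <- filter_low_counts(x, 10)
  expect_equal(f$gene_ids, "hi")
  expect_equal(attr(f, "dropped_genes"), "lo")
  expect_equal(dim(filter_low_counts(x, 0)), dim(x))
  expect_warning(filter_low_counts(x, 1e9), "all genes")
})

test_that("DE filter applies |l2fc| and adjusted-p thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    l2fc = c(2.5, -2.5, 3, 1.9),
                    adj_p = c(0.01, 0.01, 0.2, 0.001))
  class(tab) <- c("L2FCTable", "data.frame")
  expect_setequal(de_filter(tab), c("a", "b"))
  tab$adj_p <- NULL
  expect_error(de_filter(tab), "adj_p")
  expect_setequal(de_filter(tab, require_p = FALSE), c("a", "b", "c"))
})
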