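# Brute-force oracles: explicit pair/loop enumeration of each estimator's
# defining formulas, kept independent of the vectorized implementations.

oracle_genorm_M <- function(ct) {
  genes <- rownames(ct)
  lq <- log2(2^(apply(ct, 1, min) - ct))
  sapply(genes, function(g) {
    others <- setdiff(genes, g)
    mean(sapply(others, function(h) sd(lq[g, ] - lq[h, ])))
  })
}

oracle_delta_ct <- function(ct) {
  genes <- rownames(ct)
  sapply(genes, function(g) {
    mean(sapply(setdiff(genes, g), function(h) sd(ct[g, ] - ct[h, ])))
  })
}

oracle_bestkeeper <- function(ct) {
  genes <- rownames(ct)
  idx <- sapply(seq_len(ncol(ct)), function(s) prod(ct[, s])^(1 / nrow(ct)))
  data.frame(gene = genes,
             sd = sapply(genes, function(g) sd(ct[g, ])),
             cv_pct = sapply(genes, function(g) 100 * sd(ct[g, ]) / mean(ct[g, ])),
             r = sapply(genes, function(g) cor(ct[g, ], idx)))
}

# Closed-form two-group model-based estimator, re-derived step by step.
oracle_normfinder <- function(ct, groups) {
  x <- -ct
  k <- nrow(ct)
  glev <- unique(groups)
  sig2 <- d <- matrix(NA_real_, k, length(glev))
  nvec <- integer(length(glev))
  for (gi in seq_along(glev)) {
    X <- x[, groups == glev[gi], drop = FALSE]
    n <- ncol(X); nvec[gi] <- n
    z <- X
    for (j in seq_len(n)) z[, j] <- X[, j] - mean(X[, j])
    s2 <- numeric(k)
    for (i in seq_len(k)) s2[i] <- var(z[i, ])
    S <- sum(s2)
    for (i in seq_len(k)) {
      sig2[i, gi] <- max((s2[i] - S / (k * (k - 1))) * k / (k - 2), 0)
    }
    for (i in seq_len(k)) d[i, gi] <- mean(z[i, ])
  }
  cmat <- d - rowMeans(d)
  varg <- sweep(sig2, 2, nvec, "/")
  gamma2 <- max(0, sum(cmat^2) / ((k - 1) * (length(glev) - 1)) - mean(varg))
  ctilde <- cmat * (if (gamma2 > 0) gamma2 / (gamma2 + varg) else 0)
  rowMeans(abs(ctilde)) + sqrt(rowMeans(varg))
}

test_that("geNorm M matches the pairwise brute force and degenerate cases", {
  # constant Ct offset between two genes: zero-variance log ratio
  ct2 <- rbind(a = c(20, 22, 24, 21), b = c(23, 25, 27, 24))
  colnames(ct2) <- paste0("s", 1:4)
  gn2 <- genorm(ct2)
  expect_equal(unname(gn2$M), c(0, 0))

  grids <- list(toy_ct_grid(3, 4, seed = 1), toy_ct_grid(4, 6, seed = 2))
  for (ct in grids) {
    gn <- genorm(ct)
    expect_equal(gn$M, oracle_genorm_M(ct), tolerance = 1e-9)
  }
})

test_that("geNorm is invariant to per-sample global Ct shifts and reordering", {
  ct <- toy_ct_grid(4, 6, seed = 3)
  base <- genorm(ct)
  shifted <- ct
  shifted[, 2] <- shifted[, 2] + 3.7   # same shift for every gene in sample 2
  expect_equal(genorm(shifted)$M, base$M, tolerance = 1e-9)
  perm <- ct[, c(4, 1, 6, 2, 5, 3)]
  expect_equal(genorm(perm)$M, base$M, tolerance = 1e-9)
})

test_that("geNorm stepwise exclusion removes the least stable gene first", {
  ct <- toy_ct_grid(3, 5, seed = 4)
  # make g3 erratic relative to the tight g1/g2 pair
  ct[1, ] <- 20 + c(0.0, 0.1, -0.1, 0.05, 0.0)
  ct[2, ] <- 25 + c(0.05, 0.1, -0.05, 0.0, 0.1)
  ct[3, ] <- 22 + c(3, -2, 4, -1, 2)
  gn <- genorm(ct)
  expect_equal(gn$exclusion_order[1], "g3")
  expect_equal(sort(gn$stability_order[1:2]), c("g1", "g2"))
  expect_named(gn$V, "V2/3")
  expect_gt(unname(gn$V["V2/3"]), 0)
})

test_that("comparative delta-Ct matches brute force and its invariances", {
  ct2 <- rbind(a = c(20, 22, 24), b = c(22, 24, 26))
  colnames(ct2) <- paste0("s", 1:3)
  expect_equal(unname(delta_ct_method(ct2)), c(0, 0))

  ct <- toy_ct_grid(3, 4, seed = 5)
  expect_equal(delta_ct_method(ct), oracle_delta_ct(ct), tolerance = 1e-9)
  expect_equal(delta_ct_method(ct[, c(3, 1, 4, 2)]), delta_ct_method(ct),
               tolerance = 1e-12)

  # on 2-gene instances geNorm M equals the delta-Ct statistic
  expect_equal(unname(genorm(ct2)$M), unname(delta_ct_method(ct2)),
               tolerance = 1e-12)
  ctpair <- toy_ct_grid(2, 6, seed = 6)
  expect_equal(unname(genorm(ctpair)$M), unname(delta_ct_method(ctpair)),
               tolerance = 1e-9)
})

test_that("BestKeeper stats match the spreadsheet oracle", {
  ct <- toy_ct_grid(3, 5, seed = 7)
  bk <- bestkeeper(ct)
  orc <- oracle_bestkeeper(ct)
  expect_equal(bk$sd, orc$sd, tolerance = 1e-9)
  expect_equal(bk$cv_pct, orc$cv_pct, tolerance = 1e-9)
  expect_equal(bk$r, orc$r, tolerance = 1e-9)

  # a gene equal to the index correlates perfectly
  idx <- attr(bk, "index")
  ct2 <- rbind(ct, g4 = idx)
  bk2 <- bestkeeper(ct2)
  expect_gt(bk2$r[bk2$gene == "g4"], 0.999)

  # constant gene: SD and CV% are zero, correlation undefined
  ct3 <- rbind(ct, flat = rep(25, 5))
  bk3 <- bestkeeper(ct3)
  expect_equal(bk3$sd[bk3$gene == "flat"], 0)
  expect_equal(bk3$cv_pct[bk3$gene == "flat"], 0)
  expect_true(is.na(bk3$r[bk3$gene == "flat"]))
})

test_that("NormFinder matches the closed-form oracle on a 3x6 grid", {
  ct <- toy_ct_grid(3, 6, seed = 8)
  groups <- rep(c("Hx", "Nx"), each = 3)
  expect_equal(as.numeric(normfinder(ct, groups)),
               as.numeric(oracle_normfinder(ct, groups)), tolerance = 1e-9)
  ct2 <- toy_ct_grid(5, 8, seed = 9)
  groups2 <- rep(c("Hx", "Nx"), each = 4)
  expect_equal(as.numeric(normfinder(ct2, groups2)),
               as.numeric(oracle_normfinder(ct2, groups2)), tolerance = 1e-9)
})

test_that("NormFinder ranks a constant gene best and a group-shifted gene worst", {
  set.seed(10)
  n <- 4
  groups <- rep(c("Hx", "Nx"), each = n)
  ct <- rbind(
    flat = rep(24, 2 * n),
    g2 = 26 + rnorm(2 * n, 0, 0.3),
    g3 = 28 + rnorm(2 * n, 0, 0.3),
    shifted = 25 + c(rep(2, n), rep(0, n)) + rnorm(2 * n, 0, 0.1))
  colnames(ct) <- paste0("s", 1:(2 * n))
  nf <- normfinder(ct, groups)
  expect_equal(names(which.min(nf)), "flat")
  expect_equal(names(which.max(nf)), "shifted")
  # a group with one sample is a hard error naming the group
  expect_error(normfinder(ct[, 1:5], rep(c("Hx", "Nx"), c(4, 1))), "Nx")
})

test_that("NormFinder intragroup statistics ignore global per-sample shifts", {
  ct <- toy_ct_grid(4, 8, seed = 12)
  groups <- rep(c("Hx", "Nx"), each = 4)
  shifted <- ct
  shifted[, 5] <- shifted[, 5] + 2.5
  a <- normfinder(ct, groups)
  b <- normfinder(shifted, groups)
  expect_equal(attr(a, "intragroup_var"), attr(b, "intragroup_var"),
               tolerance = 1e-9)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-9)
})

test_that("RefFinder aggregation takes geometric means with delta-Ct ties", {
  ranks <- cbind(genorm = c(1, 2, 3), normfinder = c(1, 2, 3),
                 bestkeeper = c(1, 3, 2), delta_ct = c(1, 2, 3))
  rownames(ranks) <- c("a", "b", "c")
  rf <- reffinder_aggregate(ranks)
  expect_equal(unname(rf$geomean["a"]), 1)
  expect_equal(unname(rf$rank), c(1, 2, 3))

  ranks2 <- cbind(genorm = c(1, 2), normfinder = c(2, 1),
                  bestkeeper = c(1, 2), delta_ct = c(4, 1))
  # geomeans: a = (1*2*1*4)^(1/4) = 8^(1/4), b = (2*1*2*1)^(1/4) = 4^(1/4)
  rownames(ranks2) <- c("a", "b")
  # not a complete ranking (delta_ct has rank 4 in a 2-gene set)
  expect_error(reffinder_aggregate(ranks2), "complete")
  ranks3 <- cbind(genorm = c(1, 2, 3, 4), normfinder = c(2, 1, 3, 4),
                  bestkeeper = c(1, 2, 3, 4), delta_ct = c(4, 1, 2, 3))
  rownames(ranks3) <- letters[1:4]
  rf3 <- reffinder_aggregate(ranks3)
  expect_equal(unname(rf3$geomean["a"]), 8^(1 / 4), tolerance = 1e-12)

  # reversing every method ranking reverses the final order
  rev3 <- 5 - ranks3
  rfr <- reffinder_aggregate(rev3)
  expect_equal(unname(rfr$rank), unname(5 - rf3$rank))
  expect_error(reffinder_aggregate(ranks3[, 1:3]), "delta_ct")
})

test_that("pairwise-complete handling skips pairs with < 2 common samples", {
  ct <- toy_ct_grid(3, 4, seed = 13)
  ct[1, 1:3] <- NA   # g1 shares only one sample with the others
  expect_warning(gn <- genorm(ct), "common samples")
  expect_true(is.na(gn$M["g1"]))
  expect_false(anyNA(gn$M[c("g2", "g3")]))
})
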