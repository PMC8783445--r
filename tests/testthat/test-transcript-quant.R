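test_that("rpkm follows its definition and scaling", {
  counts <- matrix(c(10, 0), nrow = 2, ncol = 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  r <- rpkm(counts, gene_lengths = c(1000, 2000), lib_sizes = 1e6)
  expect_equal(r["g1", 1], 10)
  expect_equal(r["g2", 1], 0)
  # doubling the library size halves RPKM
  r2 <- rpkm(counts, gene_lengths = c(1000, 2000), lib_sizes = 2e6)
  expect_equal(r2["g1", 1], 5)
  expect_error(rpkm(counts, gene_lengths = c(0, 10), lib_sizes = 1), "lengths")
})

test_that("Welch t matches an independent textbook computation", {
  x <- rbind(gene = c(9, 10, 11, 19, 20, 21))
  groups <- factor(rep(c("a", "b"), each = 3))
  p_pkg <- welch_t(x, groups)
  # hand computation: means 10/20, s^2 = 1 each, n = 3
  tstat <- (10 - 20) / sqrt(1 / 3 + 1 / 3)
  df <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(unname(p_pkg), p_hand, tolerance = 1e-12)
  # identical groups: p = 1
  x2 <- rbind(g = c(5, 6, 7, 5, 6, 7))
  expect_equal(unname(welch_t(x2, groups)), 1, tolerance = 1e-8)
})

test_that("paired t uses the pairing and degenerate genes return NA", {
  set.seed(20)
  base <- rnorm(6, sd = 5)
  # within-pair shift of ~1 with small pair-level noise; the large shared
  # baseline variance drowns the effect for the unpaired test
  x <- rbind(g = c(base + 1 + rnorm(6, sd = 0.05), base))
  groups <- factor(rep(c("a", "b"), each = 6))
  p_paired <- paired_t(x, groups, pairs = rep(1:6, 2))
  p_welch <- welch_t(x, groups)
  expect_lt(p_paired, p_welch)          # pairing absorbs the shared noise
  expect_lt(p_paired, 1e-6)
  xc <- rbind(g = rep(3, 12))
  expect_true(is.na(welch_t(xc, groups)))
})

test_that("one-way F needs 3 groups and detects a shifted group", {
  set.seed(21)
  x <- rbind(null = rnorm(9),
             shift = c(rnorm(3), rnorm(3) + 5, rnorm(3)))
  g3 <- factor(rep(letters[1:3], each = 3))
  p <- oneway_f(x, g3)
  expect_gt(p["null"], 0.05)
  expect_lt(p["shift"], 0.01)
  expect_error(oneway_f(x, factor(rep("a", 9))), "3 groups")
  # agreement with stats::oneway.test on one gene
  expect_equal(unname(p["shift"]),
               stats::oneway.test(x["shift", ] ~ g3, var.equal = TRUE)$p.value)
})

test_that("null Welch p-values are uniform (KS)", {
  set.seed(22)
  x <- matrix(rnorm(4000 * 10), nrow = 4000)
  p <- welch_t(x, factor(rep(c("a", "b"), each = 5)))
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("BH adjustment equals brute force exactly and handles hand example", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      r <- which(o == i)              # rank of p[i]
      q[i] <- min(1, min(p[o[r:m]] * m / (r:m)))
    }
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.007), 0.007)
  set.seed(23)
  for (rep in 1:5) {
    p <- runif(sample(10:1000, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  # q >= p and q is monotone in p-rank
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("planted strong DEGs are recovered and the null stays quiet", {
  em <- simulate_expression(n_genes = 2000, n_planted_deg = 32,
                            effect_log2fc = 3, n_pairs = 5, seed = 30)
  de <- differential_expression(em)
  truth <- em$truth$is_deg
  sens <- sum(de$table$significant & truth) / sum(truth)
  expect_gte(sens, 0.9)
  fdp <- sum(de$table$significant & !truth) /
    max(1, sum(de$table$significant))
  expect_lte(fdp, 0.15)
  # all-null matrix: essentially nothing declared
  null_counts <- vapply(1:5, function(s) {
    em0 <- simulate_expression(n_genes = 1000, n_planted_deg = 0,
                               effect_log2fc = 0, n_pairs = 5,
                               allele_rule = FALSE, seed = 40 + s)
    sum(differential_expression(em0)$table$significant)
  }, numeric(1))
  expect_equal(median(null_counts), 0)
})

test_that("allele-dosage construction is visible in RPKM space", {
  em <- simulate_expression(n_pairs = 5, seed = 31)
  r <- rpkm(em)
  neg <- em$groups == "EYFP_neg"
  ratio <- mean(r["Cx3cr1", neg]) / mean(r["Cx3cr1", !neg])
  expect_lt(abs(ratio - 2), 0.5)
  expect_true(all(r["Cre", neg] == 0))
  expect_true(all(r["Eyfp", neg] == 0))
  expect_true(all(r["Cre", !neg] > 0))
  # exchangeable groups when nothing is planted
  em0 <- simulate_expression(n_genes = 500, n_planted_deg = 0,
                             effect_log2fc = 0, allele_rule = FALSE,
                             seed = 32)
  expect_equal(dim(em0$counts), c(500L, 10L))
  expect_false(any(em0$truth$is_deg))
})

test_that("zero-variance genes are excluded with a flag, not tested", {
  em <- simulate_expression(n_genes = 200, n_planted_deg = 5, seed = 33)
  em$counts[10, ] <- 0                       # all-zero gene
  de <- differential_expression(em)
  expect_true(de$table$excluded[10])
  expect_true(is.na(de$table$p[10]))
  expect_false(de$table$significant[10])
})

test_that("row z-scoring standardises and drops constants", {
  set.seed(25)
  x <- rbind(a = rnorm(8, 5, 2), b = rnorm(8, -3, 0.5), c = rep(4, 8))
  z <- zscore_rows(x)
  expect_identical(rownames(z), c("a", "b"))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_identical(attr(z, "dropped"), "c")
})

test_that("PCA separates duplicated sample groups on PC1", {
  set.seed(26)
  va <- rnorm(300); vb <- rnorm(300)
  x <- cbind(va, va, va, vb, vb, vb) + matrix(rnorm(1800, sd = 1e-3), 300)
  colnames(x) <- paste0("s", 1:6)
  ps <- pca_scores(x)
  s1 <- ps$scores[, 1]
  expect_gt(min(abs(mean(s1[1:3]) - mean(s1[4:6]))), 1)
  expect_lt(max(sd(s1[1:3]), sd(s1[4:6])), 0.1)
  # prefilter keeps only small-p genes
  gp <- c(rep(0.001, 50), rep(0.5, 250))
  ps2 <- pca_scores(x, gene_p = gp, p_cutoff = 0.05)
  expect_identical(ps2$n_genes_used, 50L)
  # sign convention: largest-magnitude loading positive
  expect_gt(ps$loadings[which.max(abs(ps$loadings[, 1])), 1], 0)
})
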