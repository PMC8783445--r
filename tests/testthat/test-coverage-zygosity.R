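# Brute-force oracle: per-base span counting.
naive_coverage <- function(spans, len) {
  c0 <- integer(len)
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, 1]; e <- spans[i, 2]
    if (e > s) c0[(s + 1):e] <- c0[(s + 1):e] + 1L
  }
  c0
}

fake_alignment_set <- function(spans, contig = "genome", len = 200L) {
  n <- nrow(spans)
  contig <- rep_len(contig, n)
  rec <- data.frame(
    template_id = sprintf("t%03d", seq_len(n)),
    r1_contig = contig, r1_pos = spans[, 1], r1_strand = rep_len("+", n),
    r1_mm = rep_len(0L, n), r1_mapq = rep_len(60L, n),
    r2_contig = contig, r2_pos = spans[, 2] - 10L, r2_strand = rep_len("-", n),
    r2_mm = rep_len(0L, n), r2_mapq = rep_len(60L, n),
    contig = contig, fragment_start = spans[, 1], fragment_end = spans[, 2],
    proper = rep_len(TRUE, n), mapq = rep_len(60L, n),
    duplicate = rep_len(FALSE, n), bqsum = rep_len(100L, n),
    stringsAsFactors = FALSE)
  structure(list(records = rec,
                 contig_len = stats::setNames(as.integer(len),
                                              if (n > 0) contig[1] else "genome"),
                 read_len = 10L, fragment_mean = 50, provenance = character(0)),
            class = "alignment_set")
}

test_that("difference-array coverage equals naive per-base counting exactly", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 50
    s <- sample.int(150, n, replace = TRUE) - 1L
    e <- pmin(s + sample(5:40, n, replace = TRUE), 200L)
    spans <- cbind(s, e)
    track <- physical_coverage(fake_alignment_set(spans), "genome")
    expect_identical(track$counts, naive_coverage(spans, 200L))
    # conservation: sum of coverage equals total fragment length
    expect_identical(sum(track$counts), sum(e - s))
  }
})

test_that("coverage handles worked examples and empty input", {
  spans <- rbind(c(10L, 60L), c(40L, 90L))
  track <- physical_coverage(fake_alignment_set(spans), "genome")
  expect_identical(track$counts[51], 2L)  # C(50), 0-based base 50
  expect_identical(track$counts[6], 0L)   # C(5)
  expect_identical(track$counts[90], 1L)  # C(89)
  empty <- fake_alignment_set(cbind(integer(0), integer(0)))
  expect_true(all(physical_coverage(empty, "genome")$counts == 0L))
  expect_error(physical_coverage(empty, "nope"), "unknown contig")
})

test_that("region mean coverage matches brute force and validates regions", {
  set.seed(9)
  spans <- cbind(s <- sample.int(150, 80, TRUE) - 1L,
                 pmin(s + sample(10:50, 80, TRUE), 200L))
  aln <- fake_alignment_set(spans)
  track <- physical_coverage(aln, "genome")
  ref_counts <- naive_coverage(spans, 200L)
  expect_equal(region_mean_coverage(track, c(30L, 70L)),
               mean(ref_counts[31:70]))
  norm <- region_mean_coverage(track, c(30L, 70L), normalize = TRUE)
  expect_equal(norm, mean(ref_counts[31:70]) / (nrow(spans) / 1e6))
  expect_error(region_mean_coverage(track, c(50L, 50L)), "zero-length")
  uniform <- fake_alignment_set(rbind(c(0L, 200L), c(0L, 200L),
                                      c(0L, 200L), c(0L, 200L)))
  expect_equal(region_mean_coverage(physical_coverage(uniform, "genome"),
                                    c(20L, 80L)), 4)
})

test_that("dosage estimates follow the two-per-copy anchor", {
  d <- estimate_dosage(cov_exon2 = 12, cov_cassette = 0, cov_flank = 12)
  expect_equal(d$wt_dosage, 2)
  expect_equal(d$ki_dosage, 0)
  d2 <- estimate_dosage(cov_exon2 = 0, cov_cassette = 12, cov_flank = 12)
  expect_equal(d2$wt_dosage, 0)
  expect_equal(d2$ki_dosage, 2)
  expect_error(estimate_dosage(1, 1, 0), "flank")
})

test_that("junction evidence separates genotypes", {
  m <- fixture_model()
  ref <- fixture_reference()
  junc_for <- function(g, seed) {
    reads <- simulate_wgs_readpairs(m, g, n_fragments = 2000, seed = seed)
    aln <- mark_duplicates(map_readpairs(reads, ref))
    count_junction_pairs(filter_alignments(aln, require_proper = FALSE), ref)
  }
  jw <- junc_for("WT_WT", 31)
  expect_identical(jw$n_ki_supporting, 0L)
  expect_gt(jw$n_wt_spanning, 0L)
  jk <- junc_for("KI_KI", 32)
  # a read overhanging the junction by a few bases can still map within the
  # mismatch budget, so the wt-spanning count is ~0 (vs ~14 for the het)
  expect_lte(jk$n_wt_spanning, 3L)
  expect_gt(jk$n_ki_supporting, 0L)
  jh <- junc_for("KI_WT", 33)
  expect_gt(jh$n_wt_spanning, 0L)
  expect_gt(jh$n_ki_supporting, 0L)
})

test_that("genotype calls recover the truth at 30x with high confidence", {
  m <- fixture_model()
  for (g in c("WT_WT", "KI_WT", "KI_KI")) {
    res <- wgs_zygosity_pipeline(m, g, depth = 30, seed = 77)
    expect_identical(res$call$genotype, g)
    expect_gt(res$call$llr, 10)
  }
})

test_that("het exon dosage sits near one at 30x depth", {
  m <- fixture_model()
  res <- wgs_zygosity_pipeline(m, "KI_WT", depth = 30, seed = 78)
  expect_lt(abs(res$dosage$wt_dosage - 1), 0.35)
  expect_lt(abs(res$dosage$ki_dosage - 1), 0.35)
})

test_that("parameter recovery: calls stay accurate down to 3x depth", {
  m <- fixture_model()
  confusion <- table(truth = character(0), call = character(0))
  correct30 <- 0L
  for (g in c("WT_WT", "KI_WT", "KI_KI")) {
    for (s in 1:10) {
      call <- wgs_zygosity_pipeline(m, g, depth = 30,
                                    seed = 500 + s)$call$genotype
      correct30 <- correct30 + (call == g)
    }
  }
  expect_identical(correct30, 30L)
  calls3 <- matrix("", 3, 50,
                   dimnames = list(c("WT_WT", "KI_WT", "KI_KI"), NULL))
  for (g in rownames(calls3)) {
    for (s in 1:50) {
      calls3[g, s] <- wgs_zygosity_pipeline(m, g, depth = 3,
                                            seed = 900 + s)$call$genotype
    }
  }
  acc3 <- mean(calls3 == rownames(calls3)[row(calls3)])
  expect_gte(acc3, 0.9)
})

test_that("no-call when the flank anchor is empty", {
  expect_error(depth_model(0, 16000, 1500, 5000), "no-call")
})

test_that("bedGraph export covers the contig in order", {
  aln <- fake_alignment_set(rbind(c(0L, 50L), c(25L, 120L)))
  track <- physical_coverage(aln, "genome")
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(track, f)
  tb <- read.table(f, sep = "\t")
  expect_identical(tb$V2[1], 0L)
  expect_identical(tb$V3[nrow(tb)], 200L)
  # reconstruct the track from the intervals
  recon <- integer(200)
  for (i in seq_len(nrow(tb))) recon[(tb$V2[i] + 1):tb$V3[i]] <- tb$V4[i]
  expect_identical(recon, track$counts)
})
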