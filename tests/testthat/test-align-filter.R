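test_that("error-free wild-type reads map as proper pairs on the genome contig", {
  m <- fixture_model()
  ref <- fixture_reference()
  reads <- simulate_wgs_readpairs(m, "WT_WT", n_fragments = 400,
                                  error_rate = 0, seed = 21)
  aln <- map_readpairs(reads, ref)
  r <- aln$records
  expect_gte(mean(r$proper), 0.99)
  expect_true(all(r$contig[r$proper] == "genome"))
  # mapped positions recover the simulated fragment spans
  ok <- which(r$proper)
  expect_true(all(r$fragment_start[ok] == reads$reads$start[ok]))
  expect_true(all(r$fragment_end[ok] ==
                    reads$reads$start[ok] + reads$reads$fragment_length[ok]))
})

test_that("reads from the cassette interior map to the cassette contig", {
  ref <- fixture_reference()
  cass <- ref$contigs[["cassette_nongenomic"]]
  r1 <- substr(cass, 2001, 2075)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(cass, 2201, 2275))))
  aln <- map_readpairs(manual_readpairs(r1, r2), ref)
  expect_identical(aln$records$contig, "cassette_nongenomic")
  expect_true(aln$records$proper)
  expect_identical(aln$records$mapq, 60L)
})

test_that("a read inside a segment duplicated on both contigs gets MAPQ 0", {
  ref <- make_duplicated_reference()
  g <- ref$contigs[["genome"]]
  r1 <- substr(g, 901, 975)    # inside the shared 400 bp segment
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(g, 1101, 1175))))
  aln <- map_readpairs(manual_readpairs(r1, r2), ref)
  expect_identical(aln$records$r1_mapq, 0L)
})

test_that("duplicate marking matches a brute-force key grouping and is idempotent", {
  aln <- fixture_alignments()
  r <- aln$records
  p <- r[r$proper, ]
  orient <- ifelse(p$r1_pos <= p$r2_pos, paste0(p$r1_strand, p$r2_strand),
                   paste0(p$r2_strand, p$r1_strand))
  key <- paste(p$contig, p$fragment_start, p$fragment_end, orient)
  expected_flagged <- sum(table(key) - 1)
  expect_identical(sum(r$duplicate), as.integer(expected_flagged))
  # within every key exactly one record is kept
  kept <- p$template_id[!r$duplicate[r$proper]]
  expect_identical(length(kept), length(unique(key)))
  # idempotent, never removes records
  again <- mark_duplicates(aln)
  expect_identical(again$records, aln$records)
  expect_identical(nrow(again$records), nrow(r))
})

test_that("dup_rate zero yields no flagged duplicates beyond chance collisions", {
  m <- fixture_model()
  ref <- fixture_reference()
  reads <- simulate_wgs_readpairs(m, "WT_WT", n_fragments = 400, dup_rate = 0,
                                  seed = 23)
  aln <- mark_duplicates(map_readpairs(reads, ref))
  expect_lte(sum(aln$records$duplicate), 2)
})

test_that("filtering drops by threshold and reasons are conserved", {
  aln <- fixture_alignments()
  # threshold logic on a constructed MAPQ vector: keep {20, 60}, drop {0, 19}
  toy <- aln
  toy$records <- toy$records[toy$records$proper, ][1:4, ]
  toy$records$mapq <- c(0L, 19L, 20L, 60L)
  toy$records$duplicate <- FALSE
  kept <- filter_alignments(toy, mapq_min = 20)
  expect_identical(kept$records$mapq, c(20L, 60L))

  out <- filter_alignments(aln)
  r <- aln$records
  log <- out$provenance[length(out$provenance)]
  nums <- as.integer(regmatches(log, gregexpr("[0-9]+", log))[[1]])
  # input = duplicate + mapq + improper + output (reason counts conserve)
  expect_identical(nums[1], nums[2] + nums[4] + nums[5] + nums[6])
  expect_identical(nums[6], nrow(out$records))
  # output only proper, non-duplicate, mapq-passing pairs
  expect_true(all(out$records$proper))
  expect_false(any(out$records$duplicate))
  expect_true(all(out$records$mapq >= 20))
})

test_that("filtering is order-independent", {
  aln <- fixture_alignments()
  set.seed(1)
  shuf <- aln
  shuf$records <- shuf$records[sample.int(nrow(shuf$records)), ]
  a <- sort(filter_alignments(aln)$records$template_id)
  b <- sort(filter_alignments(shuf)$records$template_id)
  expect_identical(a, b)
})

test_that("mark_duplicates flags only and filter_alignments removes only", {
  aln <- fixture_alignments()
  expect_identical(nrow(mark_duplicates(aln)$records), nrow(aln$records))
  out <- filter_alignments(aln, drop_duplicates = FALSE, mapq_min = 0,
                           require_proper = FALSE)
  expect_identical(sum(out$records$duplicate), sum(aln$records$duplicate))
})

test_that("SAM round-trip preserves spans, MAPQ and flags", {
  aln <- fixture_alignments()
  f <- tempfile(fileext = ".sam")
  write_sam(aln, f)
  back <- read_sam(f)
  a <- aln$records[order(aln$records$template_id), ]
  b <- back$records[order(back$records$template_id), ]
  expect_identical(nrow(a), nrow(b))
  expect_identical(b$fragment_start, a$fragment_start)
  expect_identical(b$fragment_end, a$fragment_end)
  expect_identical(b$mapq, a$mapq)
  expect_identical(b$proper, a$proper)
  expect_identical(b$duplicate, a$duplicate)
  # POS is 1-based on disk, 0-based internally
  body <- readLines(f)
  body <- body[!startsWith(body, "@")]
  first <- strsplit(body[1], "\t")[[1]]
  id1 <- first[1]
  pos_disk <- as.integer(first[4])
  rec <- aln$records[aln$records$template_id == id1, ]
  expect_identical(pos_disk, rec$r1_pos + 1L)
})

test_that("empty or headerless SAM inputs behave as specified", {
  aln <- fixture_alignments()
  empty <- aln
  empty$records <- empty$records[0, ]
  f <- tempfile(fileext = ".sam")
  write_sam(empty, f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "@")))
  back <- read_sam(f)
  expect_identical(nrow(back$records), 0L)
  g <- tempfile(fileext = ".sam")
  writeLines("@HD\tVN:1.6", g)
  expect_error(read_sam(g), "@SQ")
})
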